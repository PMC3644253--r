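#' Read and write genotype matrices as TSV
#'
#' The TSV layout is one row per site: `site_id`, `arm`, `pos`, `ref`,
#' `alt`, `cov`, then one 0/1 column per line (column name = line id;
#' missing genotypes blank/NA).  LD-block and inversion labels, when
#' present, ride along as `ld_block` / `inversion` columns.
#'
#' @param geno A `sleepqg_genotypes` object.
#' @param path Output/input file path.
#' @return `write_genotypes_tsv`: the path, invisibly.
#'   `read_genotypes_tsv`: a `sleepqg_genotypes` object (karyotypes are not
#'   stored in the TSV and come back NULL).
#' @export
write_genotypes_tsv <- function(geno, path) {
  stopifnot(inherits(geno, "sleepqg_genotypes"))
  meta_cols <- intersect(c("site_id", "arm", "pos", "ref", "alt", "cov",
                           "ld_block", "inversion"), names(geno$sites))
  tab <- cbind(geno$sites[, meta_cols, drop = FALSE],
               as.data.frame(t(geno$geno)))
  data.table::fwrite(tab, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tab <- as.data.frame(data.table::fread(path, sep = "\t"))
  meta_cols <- intersect(c("site_id", "arm", "pos", "ref", "alt", "cov",
                           "ld_block", "inversion"), names(tab))
  lines <- setdiff(names(tab), meta_cols)
  G <- t(as.matrix(tab[, lines, drop = FALSE]))
  storage.mode(G) <- "integer"
  colnames(G) <- tab$site_id
  sites <- tab[, meta_cols, drop = FALSE]
  if (is.null(sites$ld_block)) sites$ld_block <- NA_character_
  if (is.null(sites$inversion)) sites$inversion <- NA_character_
  n_used <- colSums(!is.na(G))
  alt_n <- colSums(G, na.rm = TRUE)
  sites$minor_lines <- pmin(alt_n, n_used - alt_n)
  sites$maf <- sites$minor_lines / n_used
  structure(list(geno = G, sites = sites, karyotypes = NULL,
                 inversions = NULL),
            class = "sleepqg_genotypes")
}

#' Write a genotype matrix as a minimal haploid-style VCF
#'
#' VCFv4.2 with one haploid GT column per line (0 or 1; "." for missing)
#' and coverage in INFO (`DP=`).  This is the emission dialect of the
#' simulator, not a general VCF writer.
#'
#' @param geno A `sleepqg_genotypes` object.
#' @param path Output path (uncompressed).
#' @return The path, invisibly.
#' @export
write_vcf_minimal <- function(geno, path) {
  stopifnot(inherits(geno, "sleepqg_genotypes"))
  s <- geno$sites
  gt <- t(geno$geno)
  gt_chr <- matrix(as.character(gt), nrow(gt), ncol(gt))
  gt_chr[is.na(gt)] <- "."
  body <- cbind(s$arm, s$pos, s$site_id, s$ref, s$alt, ".", "PASS",
                paste0("DP=", s$cov), "GT", gt_chr)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=sleepqg simulate_genotypes",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(geno$geno)),
                     collapse = "\t")), con)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' Write inversion intervals as BED with a carrier sidecar TSV
#'
#' BED columns: arm, start, end, inversion name.  The sidecar
#' (`<path>.carriers.tsv`) has columns `inversion`, `line`, `carrier`.
#'
#' @param geno A `sleepqg_genotypes` with non-NULL `inversions` and
#'   `karyotypes`.
#' @param bed_path BED output path.
#' @return Invisibly, `c(bed_path, sidecar_path)`.
#' @export
write_inversions_bed <- function(geno, bed_path) {
  inv <- geno$inversions
  if (is.null(inv)) stop("no inversions in this genotype object")
  bed <- data.frame(inv$arm, as.integer(inv$start), as.integer(inv$end),
                    inv$name)
  data.table::fwrite(bed, bed_path, sep = "\t", col.names = FALSE)
  side <- file.path(paste0(bed_path, ".carriers.tsv"))
  car <- do.call(rbind, lapply(inv$name, function(nm)
    data.frame(inversion = nm, line = rownames(geno$karyotypes),
               carrier = as.integer(geno$karyotypes[, nm]))))
  data.table::fwrite(car, side, sep = "\t")
  invisible(c(bed_path, side))
}

#' @rdname write_inversions_bed
#' @param carriers_path Sidecar path (defaults to `<bed_path>.carriers.tsv`).
#' @return `read_inversions_bed`: list with `inversions` (data.frame
#'   `name`, `arm`, `start`, `end`) and `karyotypes` (logical lines x
#'   inversions matrix).
#' @export
read_inversions_bed <- function(bed_path, carriers_path = NULL) {
  if (is.null(carriers_path))
    carriers_path <- paste0(bed_path, ".carriers.tsv")
  bed <- as.data.frame(data.table::fread(bed_path, header = FALSE))
  names(bed) <- c("arm", "start", "end", "name")[seq_len(ncol(bed))]
  car <- as.data.frame(data.table::fread(carriers_path))
  lines <- unique(car$line)
  kary <- matrix(FALSE, length(lines), nrow(bed),
                 dimnames = list(lines, bed$name))
  kary[cbind(match(car$line, lines), match(car$inversion, bed$name))] <-
    car$carrier == 1L
  list(inversions = bed[, c("name", "arm", "start", "end")],
       karyotypes = kary)
}

#' Read or write a long phenotype table as TSV
#'
#' @param phenos Long table (`line`, `sex`, `block`, `rep`, `trait`,
#'   `value`, optionally `fly_id`).
#' @param path File path.
#' @export
write_phenotypes_tsv <- function(phenos, path) {
  data.table::fwrite(phenos, path, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}
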
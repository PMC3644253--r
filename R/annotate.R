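#' Classify sites by gene-model context from a GFF3 annotation
#'
#' Assigns each site a class by interval containment with precedence
#' CDS > 5'UTR > 3'UTR > intron > intergenic: a site inside a gene but in
#' no exon-level sub-feature is intronic.  All overlapping gene IDs are
#' reported (comma-joined).  Sites on arms absent from the annotation are
#' intergenic, with a warning.
#'
#' @param sites data.frame with `site_id`, `arm`, `pos`.
#' @param gff Path to a GFF3 file, or a `GRanges` already imported (must
#'   carry `type` and `ID` metadata columns).
#' @return data.frame: `site_id`, `site_class` (one of `intergenic`,
#'   `intron`, `CDS`, `5'UTR`, `3'UTR`), `gene_ids`.
#' @export
annotate_site_class <- function(sites, gff) {
  ann <- if (is.character(gff)) rtracklayer::import(gff) else gff
  type <- as.character(ann$type)
  gr_sites <- GenomicRanges::GRanges(
    seqnames = sites$arm,
    ranges = IRanges::IRanges(start = sites$pos, width = 1))
  if (!all(sites$arm %in% unique(as.character(GenomicRanges::seqnames(ann)))))
    warning("some sites lie on arms absent from the annotation; ",
            "classified intergenic")

  overlaps_any <- function(feature_types) {
    sel <- which(type %in% feature_types)
    if (length(sel) == 0L) return(rep(FALSE, length(gr_sites)))
    suppressWarnings(GenomicRanges::countOverlaps(gr_sites, ann[sel],
                                                  ignore.strand = TRUE)) > 0L
  }
  in_cds <- overlaps_any("CDS")
  in_utr5 <- overlaps_any(c("five_prime_UTR", "5'UTR"))
  in_utr3 <- overlaps_any(c("three_prime_UTR", "3'UTR"))
  in_gene <- overlaps_any(c("gene", "mRNA"))
  cls <- rep("intergenic", length(gr_sites))
  cls[in_gene] <- "intron"
  cls[in_utr3] <- "3'UTR"
  cls[in_utr5] <- "5'UTR"
  cls[in_cds] <- "CDS"

  gene_sel <- which(type == "gene")
  gene_ids <- rep("", length(gr_sites))
  if (length(gene_sel) > 0L) {
    ov <- suppressWarnings(
      GenomicRanges::findOverlaps(gr_sites, ann[gene_sel],
                                  ignore.strand = TRUE))
    ids <- as.character(ann$ID[gene_sel][S4Vectors::subjectHits(ov)])
    agg <- tapply(ids, S4Vectors::queryHits(ov),
                  function(x) paste(unique(x), collapse = ","))
    gene_ids[as.integer(names(agg))] <- unname(agg)
  }
  data.frame(site_id = sites$site_id, site_class = cls, gene_ids = gene_ids,
             stringsAsFactors = FALSE)
}
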
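#' Simulate a homozygous lines-by-SNPs genotype matrix
#'
#' Draws biallelic, fully homozygous sites for an inbred-line panel.  The
#' site-frequency spectrum is skewed toward rare alleles: the minor-line
#' count k is drawn from `P(k) ~ k^-sfs_shape` over `4 .. floor(n_lines/2)`,
#' so every emitted site has its minor allele in at least 4 lines and passes
#' [filter_snps()] by construction (coverage metadata is drawn in 3..29).
#' Local LD blocks are realized by copying a template column with per-line
#' flip probability `1 - copy_fidelity`; sites falling inside a declared
#' inversion interval track the per-line karyotype with fidelity
#' `inversion_fidelity`.
#'
#' @param cfg A [sim_config()] object.
#' @return An object of class `sleepqg_genotypes`: a list with
#'   \describe{
#'     \item{geno}{integer matrix, lines x sites, 0/1 allele codes
#'       (homozygous classes; 1 is the alternative allele, not necessarily
#'       the minor one).}
#'     \item{sites}{data.frame of site metadata: `site_id`, `arm`, `pos`,
#'       `ref`, `alt`, `cov`, `minor_lines`, `maf`, `ld_block`, `inversion`.}
#'     \item{karyotypes}{logical matrix, lines x inversions (or NULL).}
#'     \item{inversions}{the inversion spec with interval coordinates.}
#'   }
#' @export
simulate_genotypes <- function(cfg) {
  validate_sim_config(cfg)
  set.seed(sub_seed(cfg, "genotypes"))
  n <- cfg$n_lines
  kmin <- 4L
  kmax <- as.integer(floor(n / 2))

  ## inversion karyotypes first: per-line carrier flags, both classes >= 4
  inv <- cfg$inversion_spec
  kary <- NULL
  if (!is.null(inv)) {
    kary <- matrix(FALSE, n, nrow(inv),
                   dimnames = list(line_ids(cfg), inv$name))
    for (j in seq_len(nrow(inv))) {
      repeat {
        v <- runif(n) < inv$carrier_fraction[j]
        if (sum(v) >= 4L && sum(!v) >= 4L) break
      }
      kary[, j] <- v
    }
  }

  ## positions: LD-block members are clustered within their declared span;
  ## remaining sites are uniform over the five major arms
  lb <- cfg$ld_block_spec
  n_lb <- if (is.null(lb)) 0L else sum(lb$n_snps)
  if (n_lb > cfg$n_snps) stop("ld_block_spec requests more sites than n_snps")
  arm <- character(cfg$n_snps)
  pos <- numeric(cfg$n_snps)
  ld_block <- rep(NA_character_, cfg$n_snps)
  idx <- 1L
  if (!is.null(lb)) {
    for (b in seq_len(nrow(lb))) {
      m <- lb$n_snps[b]
      a0 <- runif(1, 1, .ARM_LEN - lb$span[b])
      take <- idx:(idx + m - 1L)
      arm[take] <- lb$arm[b]
      pos[take] <- sort(a0 + runif(m, 0, lb$span[b]))
      ld_block[take] <- sprintf("ld_%02d", b)
      idx <- idx + m
    }
  }
  if (idx <= cfg$n_snps) {
    rest <- idx:cfg$n_snps
    arm[rest] <- sample(.ARMS, length(rest), replace = TRUE)
    pos[rest] <- runif(length(rest), 1, .ARM_LEN)
  }
  pos <- round(pos)
  ## unique positions within arm
  repeat {
    dup <- duplicated(paste(arm, pos))
    if (!any(dup)) break
    pos[dup] <- pos[dup] + sample(1:1000, sum(dup), replace = TRUE)
  }

  ## which sites sit inside an inversion interval
  inversion <- rep(NA_character_, cfg$n_snps)
  if (!is.null(inv)) {
    for (j in seq_len(nrow(inv))) {
      inside <- arm == inv$arm[j] & pos >= inv$start[j] & pos <= inv$end[j]
      inversion[inside & is.na(inversion)] <- inv$name[j]
    }
  }

  kk <- kmin:kmax
  pk <- kk^(-cfg$sfs_shape)
  draw_sfs_column <- function() {
    k <- kk[sample.int(length(kk), 1L, prob = pk)]
    g <- integer(n)
    g[sample.int(n, k)] <- 1L
    g
  }
  minor_count <- function(g) min(sum(g), n - sum(g))
  ## copy a template with per-line flips, keeping the minor allele in >= 4
  ## lines (redraw flips if a rare flip pattern breaks the filter invariant)
  copy_with_flips <- function(template, fidelity) {
    for (i in 1:200) {
      g <- template
      fl <- runif(n) < (1 - fidelity)
      g[fl] <- 1L - g[fl]
      if (minor_count(g) >= 4L) return(g)
    }
    template
  }

  geno <- matrix(0L, n, cfg$n_snps, dimnames = list(line_ids(cfg), NULL))
  ## one template per LD block, drawn from the common end of the spectrum:
  ## local-LD / inversion haplotypes segregate at intermediate frequency,
  ## and per-line flips on a rare template would destroy the planted r2
  if (!is.null(lb)) {
    lo <- min(max(6L, as.integer(ceiling(0.2 * n))), kmax)
    for (b in seq_len(nrow(lb))) {
      members <- which(ld_block == sprintf("ld_%02d", b))
      kt <- (lo:kmax)[sample.int(kmax - lo + 1L, 1L)]
      template <- integer(n)
      template[sample.int(n, kt)] <- 1L
      for (s in members)
        geno[, s] <- copy_with_flips(template, lb$copy_fidelity[b])
    }
  }
  for (s in which(is.na(ld_block))) {
    if (!is.na(inversion[s])) {
      kv <- as.integer(kary[, inversion[s]])
      geno[, s] <- copy_with_flips(kv, cfg$inversion_fidelity)
    } else {
      geno[, s] <- draw_sfs_column()
    }
  }

  ord <- order(match(arm, .ARMS), pos)
  geno <- geno[, ord, drop = FALSE]
  arm <- arm[ord]; pos <- pos[ord]
  ld_block <- ld_block[ord]; inversion <- inversion[ord]

  alt_n <- colSums(geno)
  minor_lines <- pmin(alt_n, n - alt_n)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
  sites <- data.frame(site_id = sprintf("%s_%d", arm, pos),
                      arm = arm, pos = pos, ref = ref, alt = unname(alt),
                      cov = sample(3:29, cfg$n_snps, replace = TRUE),
                      minor_lines = minor_lines,
                      maf = minor_lines / n,
                      ld_block = ld_block, inversion = inversion,
                      stringsAsFactors = FALSE)
  colnames(geno) <- sites$site_id

  structure(list(geno = geno, sites = sites, karyotypes = kary,
                 inversions = inv),
            class = "sleepqg_genotypes")
}

#' @export
print.sleepqg_genotypes <- function(x, ...) {
  cat("sleepqg genotype matrix:", nrow(x$geno), "lines x",
      ncol(x$geno), "sites\n")
  cat("  MAF range:", sprintf("%.4f-%.4f", min(x$sites$maf), max(x$sites$maf)),
      "\n")
  if (!is.null(x$inversions))
    cat("  inversions:", paste(x$inversions$name, collapse = ", "), "\n")
  if (any(!is.na(x$sites$ld_block)))
    cat("  LD blocks:", length(unique(na.omit(x$sites$ld_block))), "\n")
  invisible(x)
}
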
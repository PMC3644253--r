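#' Filter sites for association testing
#'
#' Retains biallelic sites whose minor allele is present in at least
#' `min_minor_lines` non-missing lines and whose sequence coverage is
#' strictly greater than 2 and strictly less than 30.  With 168 lines the
#' minor-line rule puts the minimum testable minor allele frequency at
#' 4/168 = 0.0238.
#'
#' @param geno A `sleepqg_genotypes` object.
#' @param min_minor_lines Minimum minor-line count.
#' @param cov_range Coverage bounds, exclusive on both ends.
#' @return The filtered `sleepqg_genotypes` (possibly with zero sites).
#' @export
filter_snps <- function(geno, min_minor_lines = 4L, cov_range = c(2L, 30L)) {
  stopifnot(inherits(geno, "sleepqg_genotypes"))
  G <- geno$geno
  n_used <- colSums(!is.na(G))
  alt <- colSums(G, na.rm = TRUE)
  minor <- pmin(alt, n_used - alt)
  keep <- minor >= min_minor_lines &
    geno$sites$cov > cov_range[1] & geno$sites$cov < cov_range[2]
  geno$geno <- G[, keep, drop = FALSE]
  geno$sites <- geno$sites[keep, , drop = FALSE]
  geno$sites$minor_lines <- minor[keep]
  geno$sites$maf <- minor[keep] / n_used[keep]
  rownames(geno$sites) <- NULL
  geno
}

## Vectorized one-way ANOVA of y (per line) on every 0/1 genotype column:
## F with 1 and n-2 df, plus the two class means.  Missing genotypes are
## dropped per site (complete-case per SNP).
oneway_scan <- function(G, y) {
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0L
  storage.mode(G0) <- "double"
  Md <- M; storage.mode(Md) <- "double"
  ok <- !is.na(y)
  y0 <- ifelse(ok, y, 0)
  Md[!ok, ] <- 0; G0[!ok, ] <- 0
  n1 <- colSums(G0)
  n <- colSums(Md)
  n0 <- n - n1
  s1 <- as.numeric(crossprod(G0, y0))
  s <- as.numeric(crossprod(Md, y0))
  s2 <- as.numeric(crossprod(Md, y0^2))
  m1 <- ifelse(n1 > 0, s1 / n1, NA_real_)
  m0 <- ifelse(n0 > 0, (s - s1) / n0, NA_real_)
  ss_tot <- s2 - s^2 / n
  ss_b <- ifelse(n1 > 0 & n0 > 0, n1 * n0 / n * (m1 - m0)^2, 0)
  ss_w <- pmax(ss_tot - ss_b, 0)
  df2 <- n - 2
  F <- ifelse(ss_w > 0 & df2 > 0, ss_b / (ss_w / df2), NA_real_)
  p <- ifelse(is.na(F), 1, pf(F, 1, df2, lower.tail = FALSE))
  ## monomorphic columns: p = 1 by convention
  p[n1 == 0 | n0 == 0] <- 1
  list(F = F, p = p, mean0 = m0, mean1 = m1, n0 = n0, n1 = n1, df2 = df2)
}

#' Pooled-sex single-SNP test (split-plot mixed ANOVA)
#'
#' Tests one site against line x sex means under
#' `Y = mu + SNP + S + SNPxS + L(SNP) + e` with line random: the SNP F uses
#' MS(SNP)/MS(L(SNP)) (lines are the error stratum for genotype), the
#' SNPxS F uses MS(SNPxS)/MS(residual).  With both sexes present in every
#' line this reduces exactly to two one-way ANOVAs: of the line means (sex
#' averaged) for the SNP term, and of the within-line male-female
#' differences for the interaction; unbalanced genotype classes are handled
#' exactly by least squares within each stratum.
#'
#' @param lsm Line x sex means of one trait ([line_sex_means()]).
#' @param g Named 0/1 genotype vector (names = lines; NA allowed).
#' @return list with `p_pooled`, `p_interaction`, `F_pooled`,
#'   `F_interaction`.
#' @export
test_snp_pooled <- function(lsm, g) {
  w <- reshape_line_sex(lsm)
  gg <- g[w$line]
  use <- !is.na(gg)
  if (sum(use) < 4L) stop("need >= 2 lines per genotype class")
  sc1 <- oneway_scan(matrix(as.integer(gg[use]), ncol = 1),
                     (w$M[use] + w$F[use]) / 2)
  sc2 <- oneway_scan(matrix(as.integer(gg[use]), ncol = 1),
                     w$M[use] - w$F[use])
  if (sc1$n0 == 0 || sc1$n1 == 0)
    warning("monomorphic genotype column; p = 1 by convention")
  list(p_pooled = sc1$p, p_interaction = sc2$p,
       F_pooled = sc1$F, F_interaction = sc2$F)
}

#' Per-sex single-SNP test (reduced model)
#'
#' One-way ANOVA of one sex's line means across the two genotype classes
#' (`Y = mu + SNP + e`), equivalent to the equal-variance two-sample t-test.
#'
#' @param means data.frame with `line`, `value` for one sex.
#' @param g Named 0/1 genotype vector.
#' @return list with `p` and `F`.
#' @export
test_snp_sex <- function(means, g) {
  gg <- g[means$line]
  use <- !is.na(gg)
  sc <- oneway_scan(matrix(as.integer(gg[use]), ncol = 1),
                    means$value[use])
  if (sc$n0 == 0 || sc$n1 == 0)
    warning("monomorphic genotype column; p = 1 by convention")
  list(p = sc$p, F = sc$F)
}

## line x sex means in wide form (one row per line, both sexes required)
reshape_line_sex <- function(lsm) {
  wide <- merge(lsm[lsm$sex == "M", c("line", "value")],
                lsm[lsm$sex == "F", c("line", "value")],
                by = "line", suffixes = c(".m", ".f"))
  if (nrow(wide) == 0L) stop("pooled test requires both sexes per line")
  list(line = wide$line, M = wide$value.m, F = wide$value.f)
}

#' Benjamini-Hochberg FDR control
#'
#' Step-up q-values per trait; the significant set is `q <= fdr`.
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @param fdr Significance threshold on q.
#' @return list: `q` (same length as `p`), `significant` (logical).
#' @export
bh_fdr <- function(p, fdr = 0.01) {
  if (length(p) == 0L) return(list(q = numeric(0), significant = logical(0)))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, significant = !is.na(q) & q <= fdr)
}

#' Effect size and genetic variance of a biallelic site
#'
#' `a` is half the difference between the homozygous marker-class means,
#' signed major-minus-minor; the standardized effect is `a / sigma_P`; the
#' genetic variance explained in a panel of inbred lines is
#' `V_G = 4 p q a^2` with `p`, `q` the major- and minor-allele line
#' frequencies.
#'
#' @param mean_major,mean_minor Class means.
#' @param p,q Major and minor allele frequencies (`p + q = 1`, `q <= p`).
#' @param sigma_p Overall phenotypic standard deviation (> 0).
#' @return list: `a`, `a_over_sigmaP`, `V_G`.
#' @export
#' @examples
#' effect_and_variance(520, 480, p = 0.9, q = 0.1, sigma_p = 100)
effect_and_variance <- function(mean_major, mean_minor, p, q, sigma_p) {
  if (sigma_p <= 0) stop("sigma_p must be > 0")
  a <- (mean_major - mean_minor) / 2
  list(a = a, a_over_sigmaP = a / sigma_p, V_G = 4 * p * q * a^2)
}

#' Classify the sex structure of a significant association
#'
#' `specific`: FDR-significant in exactly one sex; `antagonistic`:
#' significant in both with opposite effect signs; `biased`: significant in
#' both, same sign, SNP-by-sex interaction p below `alpha_int`; `equal`:
#' significant in both, same sign, interaction non-significant.  Sites
#' significant in neither sex (pooled-only hits) get NA.
#'
#' @param q_m,q_f Per-sex q-values.
#' @param a_m,a_f Signed per-sex effects.
#' @param p_int SNP-by-sex interaction p-value from the pooled model.
#' @param fdr Per-sex significance threshold on q.
#' @param alpha_int Interaction significance level.
#' @return Character vector in
#'   `{"specific", "biased", "antagonistic", "equal", NA}`.
#' @export
classify_sex_effect <- function(q_m, q_f, a_m, a_f, p_int,
                                fdr = 0.01, alpha_int = 0.05) {
  sig_m <- !is.na(q_m) & q_m <= fdr
  sig_f <- !is.na(q_f) & q_f <= fdr
  out <- rep(NA_character_, length(q_m))
  out[xor(sig_m, sig_f)] <- "specific"
  both <- sig_m & sig_f
  opp <- both & sign(a_m) != sign(a_f)
  out[opp] <- "antagonistic"
  same <- both & !opp
  out[same & p_int < alpha_int] <- "biased"
  out[same & p_int >= alpha_int] <- "equal"
  out
}

#' Genome-wide single-SNP association for one trait
#'
#' Runs the pooled split-plot model and the per-sex reduced models over
#' every site of a filtered genotype matrix, applies Benjamini-Hochberg FDR
#' per p-value list, computes effects (`a`, `a/sigma_P`, `V_G = 4pqa^2`,
#' with `sigma_P` the standard deviation across line x sex means) and
#' classifies the sex structure of FDR-significant sites.
#'
#' @param geno A filtered `sleepqg_genotypes`.
#' @param phenos Long per-fly (or per-cell, for CV_E) table of one trait.
#' @param fdr FDR threshold.
#' @param alpha_int Interaction threshold for the biased/equal split.
#' @return data.frame, one row per site: positions, MAF, `p_pooled`,
#'   `p_int`, `p_m`, `p_f`, `q_pooled`, `q_m`, `q_f`, `a`, `a_m`, `a_f`,
#'   `a_over_sigmaP`, `V_G`, `sig` (pooled q <= fdr), `sex_class`,
#'   `ld_block`, `inversion`.
#' @export
gwa_trait <- function(geno, phenos, fdr = 0.01, alpha_int = 0.05) {
  stopifnot(inherits(geno, "sleepqg_genotypes"))
  lsm <- line_sex_means(phenos)
  w <- reshape_line_sex(lsm)
  G <- geno$geno[w$line, , drop = FALSE]
  ybar <- (w$M + w$F) / 2
  ydiff <- w$M - w$F
  sc_pool <- oneway_scan(G, ybar)
  sc_int <- oneway_scan(G, ydiff)
  sc_m <- oneway_scan(G, w$M)
  sc_f <- oneway_scan(G, w$F)

  sigma_p <- sd(c(w$M, w$F))
  ## major = allele carried by more lines; equal split -> allele 0
  major_is_1 <- sc_pool$n1 > sc_pool$n0
  eff_a <- function(sc) {
    a <- ifelse(major_is_1, (sc$mean1 - sc$mean0) / 2,
                (sc$mean0 - sc$mean1) / 2)
    ifelse(is.na(a), 0, a)
  }
  a <- eff_a(sc_pool); a_m <- eff_a(sc_m); a_f <- eff_a(sc_f)
  n <- sc_pool$n0 + sc_pool$n1
  q_freq <- pmin(sc_pool$n0, sc_pool$n1) / n
  p_freq <- 1 - q_freq

  bh_pool <- bh_fdr(sc_pool$p, fdr)
  bh_m <- bh_fdr(sc_m$p, fdr)
  bh_f <- bh_fdr(sc_f$p, fdr)
  res <- data.frame(
    site_id = geno$sites$site_id, arm = geno$sites$arm,
    pos = geno$sites$pos, maf = geno$sites$maf,
    p_pooled = sc_pool$p, p_int = sc_int$p, p_m = sc_m$p, p_f = sc_f$p,
    q_pooled = bh_pool$q, q_m = bh_m$q, q_f = bh_f$q,
    a = a, a_m = a_m, a_f = a_f,
    a_over_sigmaP = a / sigma_p,
    V_G = 4 * p_freq * q_freq * a^2,
    sig = bh_pool$significant,
    stringsAsFactors = FALSE)
  res$sex_class <- classify_sex_effect(res$q_m, res$q_f, res$a_m, res$a_f,
                                       res$p_int, fdr, alpha_int)
  res$ld_block <- geno$sites$ld_block
  res$inversion <- geno$sites$inversion
  attr(res, "sigma_p") <- sigma_p
  res
}

#' Expected-vs-observed quantile table for a p-value list
#'
#' @param p P-values of one trait scan.
#' @return data.frame of `-log10` expected (uniform order statistics) and
#'   observed quantiles, sorted for plotting a Q-Q curve.
#' @export
qq_table <- function(p) {
  p <- sort(p[!is.na(p)])
  m <- length(p)
  data.frame(expected = -log10((seq_len(m) - 0.5) / m),
             observed = -log10(pmax(p, .Machine$double.xmin)))
}
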
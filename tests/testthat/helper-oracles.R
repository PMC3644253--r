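## Independent oracles used across test files.  Each is deliberately written
## as plain brute force so it shares no code path with the implementation.

## zero-run scanner: enumerate qualifying sleep bouts by walking the vector
oracle_bouts <- function(counts, min_bout = 5L) {
  starts <- integer(0); lens <- integer(0)
  i <- 1L; n <- length(counts)
  while (i <= n) {
    if (counts[i] == 0) {
      j <- i
      while (j < n && counts[j + 1L] == 0) j <- j + 1L
      if (j - i + 1L >= min_bout) {
        starts <- c(starts, i); lens <- c(lens, j - i + 1L)
      }
      i <- j + 1L
    } else i <- i + 1L
  }
  data.frame(start = starts, length = lens)
}

## suffix scan for the dead-fly rule
oracle_dead <- function(counts, window = 1440L) {
  n <- length(counts)
  if (n == 0L) return(TRUE)
  from <- max(1L, n - window + 1L)
  sum(counts[from:n]) == 0
}

## haplotype-frequency LD: r2 = D^2 / (p1 q1 p2 q2); every inbred line is
## one haplotype, so haplotype frequencies are simple co-occurrence counts
oracle_r2 <- function(g1, g2) {
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  p1 <- mean(g1); p2 <- mean(g2)
  p11 <- mean(g1 == 1 & g2 == 1)
  D <- p11 - p1 * p2
  D^2 / (p1 * (1 - p1) * p2 * (1 - p2))
}

## split-plot ANOVA by generic least squares (aov with an Error stratum):
## SNP tested over lines-within-genotype, SNP x sex over the within stratum
oracle_snp_pooled <- function(lsm, g) {
  d <- lsm
  d$g <- factor(g[d$line]); d$line <- factor(d$line); d$sex <- factor(d$sex)
  d <- d[!is.na(d$g), ]
  s <- summary(aov(value ~ g * sex + Error(line), data = d))
  list(p_pooled = s[["Error: line"]][[1]]["g", "Pr(>F)"],
       p_interaction = s[["Error: Within"]][[1]]["g:sex", "Pr(>F)"])
}

## hand step-up BH: find the largest k with p_(k) <= k * alpha / m
oracle_bh_rejections <- function(p, alpha) {
  m <- length(p)
  ps <- sort(p)
  k <- which(ps <= seq_len(m) * alpha / m)
  if (length(k) == 0L) 0L else max(k)
}

## brute-force interval containment with CDS > 5'UTR > 3'UTR > intron
oracle_site_class <- function(arm, pos, feats) {
  hit <- function(tp) any(feats$type == tp & feats$arm == arm &
                            feats$start <= pos & feats$end >= pos)
  if (hit("CDS")) "CDS"
  else if (hit("five_prime_UTR")) "5'UTR"
  else if (hit("three_prime_UTR")) "3'UTR"
  else if (hit("gene")) "intron"
  else "intergenic"
}

## best single addition given a fixed prefix, by exhaustive lm enumeration
oracle_best_addition <- function(y, G, prefix) {
  cand <- setdiff(colnames(G), prefix)
  rss <- vapply(cand, function(s) {
    X <- cbind(1, G[, c(prefix, s), drop = FALSE])
    sum(lm.fit(X, y)$residuals^2)
  }, 0.0)
  names(which.min(rss))
}

## small quick panel shared by several files
quick_cfg <- function(seed = 1, ...) {
  sim_config(n_lines = 24, n_blocks = 2, n_reps_per_block = 2,
             flies_per_sex_per_rep = 4, n_snps = 60, n_causal_mean = 0,
             n_causal_var = 0, seed = seed, ...)
}
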
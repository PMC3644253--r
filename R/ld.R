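#' Pairwise linkage disequilibrium (r2) among homozygous lines
#'
#' For 0/1-coded homozygous lines, r2 is the squared Pearson correlation of
#' genotype columns over pairwise-complete lines, which equals the
#' haplotype-frequency formula `D^2 / (p1 q1 p2 q2)` in this design (every
#' line is one haplotype).  Monomorphic columns give NA rows/columns.
#'
#' @param G Lines x sites 0/1 matrix (>= 2 sites), or a
#'   `sleepqg_genotypes` object.
#' @return Symmetric matrix of r2 values with unit diagonal.
#' @export
pairwise_r2 <- function(G) {
  if (inherits(G, "sleepqg_genotypes")) G <- G$geno
  stopifnot(ncol(G) >= 2L)
  suppressWarnings(r <- cor(G, use = "pairwise.complete.obs"))
  r^2
}

#' Detect local LD blocks among significant sites
#'
#' Single-linkage chaining: two sites on the same arm join a block when
#' their r2 is at least `r2_threshold` and their distance is at most
#' `max_gap`; blocks are the transitive closure (connected components).
#' Singletons form no block.  The threshold and gap are tunable because no
#' canonical definition of a "region of local LD" exists; the defaults are
#' a conventional strong-LD cutoff.
#'
#' @param r2 Symmetric r2 matrix over the candidate sites ([pairwise_r2()]).
#' @param sites data.frame with `site_id`, `arm`, `pos` in the same order
#'   as the rows of `r2`.
#' @param r2_threshold Minimum r2 to link two sites.
#' @param max_gap Maximum distance in bp to link two sites (Inf to disable).
#' @return data.frame: `block_id`, `site_id`, `arm`, `pos`; zero rows when
#'   no block exists.
#' @export
find_ld_blocks <- function(r2, sites, r2_threshold = 0.8, max_gap = Inf) {
  m <- nrow(sites)
  stopifnot(nrow(r2) == m, ncol(r2) == m)
  if (m < 2L)
    return(data.frame(block_id = character(0), site_id = character(0),
                      arm = character(0), pos = numeric(0)))
  parent <- seq_len(m)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
    if (sites$arm[i] != sites$arm[j]) next
    if (abs(sites$pos[i] - sites$pos[j]) > max_gap) next
    if (is.na(r2[i, j]) || r2[i, j] < r2_threshold) next
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  }
  root <- vapply(seq_len(m), find, 1L)
  sizes <- table(root)
  keep <- root %in% as.integer(names(sizes)[sizes >= 2L])
  if (!any(keep))
    return(data.frame(block_id = character(0), site_id = character(0),
                      arm = character(0), pos = numeric(0)))
  ids <- match(root[keep], sort(unique(root[keep])))
  out <- data.frame(block_id = sprintf("blk_%03d", ids),
                    site_id = sites$site_id[keep], arm = sites$arm[keep],
                    pos = sites$pos[keep], stringsAsFactors = FALSE)
  out[order(out$block_id, out$pos), ]
}

#' Association of an inversion karyotype with a trait
#'
#' Two-way fixed-effects ANOVA on line x sex means,
#' `Y = mu + Inv + S + InvxS + e`, for one segregating inversion scored
#' presence/absence per line.
#'
#' @param carrier Named logical vector (names = lines): inversion present.
#' @param lsm Line x sex means of one trait.
#' @return list: `p_inv`, `p_int`, `n_carrier`, `n_noncarrier`; p-values NA
#'   (test skipped) when either karyotype class has fewer than 2 lines.
#' @export
test_inversion <- function(carrier, lsm) {
  d <- lsm
  d$inv <- carrier[d$line]
  d <- d[!is.na(d$inv), , drop = FALSE]
  n_car <- length(unique(d$line[d$inv]))
  n_non <- length(unique(d$line[!d$inv]))
  if (n_car < 2L || n_non < 2L)
    return(list(p_inv = NA_real_, p_int = NA_real_,
                n_carrier = n_car, n_noncarrier = n_non))
  if (sd(d$value) == 0)
    return(list(p_inv = 1, p_int = 1, n_carrier = n_car,
                n_noncarrier = n_non))
  a <- anova(lm(value ~ inv * sex, data = d))
  list(p_inv = a["inv", "Pr(>F)"], p_int = a["inv:sex", "Pr(>F)"],
       n_carrier = n_car, n_noncarrier = n_non)
}

#' Collapse significant sites onto proxy SNPs
#'
#' Significant sites falling inside a trait-associated inversion interval
#' are counted as one proxy per inversion; each local-LD block collapses to
#' its most significant member; remaining significant sites stand for
#' themselves.  The proxy of a group is its smallest pooled p-value, ties
#' broken by smaller genomic position.  Reports raw and collapsed counts
#' (the "N (n_proxy)" tallying convention).
#'
#' @param assoc Association table from [gwa_trait()] (uses `sig`,
#'   `p_pooled`, `inversion` membership and positions).
#' @param blocks LD-block table from [find_ld_blocks()] computed on the
#'   significant sites (may be zero-row).
#' @param assoc_inversions Character vector of inversion names associated
#'   with this trait (sites in other inversions are not collapsed by
#'   inversion, but may still fall in LD blocks).  NULL collapses every
#'   inversion with significant members.
#' @return list: `proxies` (data.frame `group`, `kind`, `n_members`,
#'   `proxy_site`), `n_raw`, `n_collapsed`.
#' @export
collapse_proxies <- function(assoc, blocks, assoc_inversions = NULL) {
  sig <- assoc[assoc$sig, , drop = FALSE]
  n_raw <- nrow(sig)
  if (n_raw == 0L)
    return(list(proxies = data.frame(group = character(0),
                                     kind = character(0),
                                     n_members = integer(0),
                                     proxy_site = character(0)),
                n_raw = 0L, n_collapsed = 0L))
  group <- rep(NA_character_, n_raw)
  kind <- rep("singleton", n_raw)
  inv <- sig$inversion
  if (is.null(assoc_inversions)) assoc_inversions <- unique(na.omit(inv))
  in_inv <- !is.na(inv) & inv %in% assoc_inversions
  group[in_inv] <- paste0("inv:", inv[in_inv])
  kind[in_inv] <- "inversion"
  if (nrow(blocks) > 0L) {
    bi <- match(sig$site_id, blocks$site_id)
    in_blk <- !is.na(bi) & is.na(group)
    group[in_blk] <- paste0("ld:", blocks$block_id[bi[in_blk]])
    kind[in_blk] <- "local_LD"
  }
  single <- is.na(group)
  group[single] <- paste0("site:", sig$site_id[single])
  proxies <- do.call(rbind, lapply(unique(group), function(g) {
    members <- which(group == g)
    best <- members[order(sig$p_pooled[members], sig$pos[members])][1]
    data.frame(group = g, kind = kind[best], n_members = length(members),
               proxy_site = sig$site_id[best], stringsAsFactors = FALSE)
  }))
  list(proxies = proxies, n_raw = n_raw, n_collapsed = nrow(proxies))
}
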
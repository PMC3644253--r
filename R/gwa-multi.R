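#' Iterative forward-selection additive multi-SNP model
#'
#' Greedy stepwise fit of `Y = mu + SNP1 + SNP2 + ... + SNPN + e` to line
#' means of one sex: step k adds the candidate with the smallest partial-F
#' p-value given the sites already in the model (equivalently the largest
#' residual sum-of-squares reduction), ties broken by genomic order.  By
#' default selection stops when adding the best candidate would decrease
#' the adjusted R2; a raw R2 ("r2 maximal") rule cannot terminate before
#' saturation, so the alternative exposed is a partial-F p-value stop.
#' Per-step R2 values are recomputed by exact least squares on the selected
#' sites, so refitting the final model reproduces them.
#'
#' @param means data.frame with `line`, `value`: per-sex line means.
#' @param geno Filtered `sleepqg_genotypes` (or a lines x sites 0/1 matrix
#'   with line rownames) providing the candidate sites.
#' @param candidates Optional character vector of site ids restricting the
#'   pool (default: all sites of `geno`).
#' @param stop_rule `"adjusted_r2"` (default) or `"partial_f"`.
#' @param alpha_stop Partial-F p threshold when `stop_rule = "partial_f"`.
#' @param max_steps Hard cap on model size.
#' @return Object of class `sleepqg_multisnp`: list with `steps`
#'   (data.frame `step`, `site_id`, `partial_p`, `r2`, `adj_r2`),
#'   `selected`, `r2`, `adj_r2`, `n_lines`.
#' @export
forward_select <- function(means, geno, candidates = NULL,
                           stop_rule = c("adjusted_r2", "partial_f"),
                           alpha_stop = 0.05, max_steps = Inf) {
  stop_rule <- match.arg(stop_rule)
  G <- if (inherits(geno, "sleepqg_genotypes")) geno$geno else geno
  if (!is.null(candidates)) G <- G[, candidates, drop = FALSE]
  G <- G[means$line, , drop = FALSE]
  y <- means$value
  n <- length(y)
  if (n < 10L) stop("forward selection requires >= 10 lines")
  m <- ncol(G)
  empty <- list(steps = data.frame(step = integer(0), site_id = character(0),
                                   partial_p = numeric(0), r2 = numeric(0),
                                   adj_r2 = numeric(0)),
                selected = character(0), r2 = 0, adj_r2 = 0, n_lines = n)
  class(empty) <- "sleepqg_multisnp"
  if (m == 0L) return(empty)

  ## residualized copies for selection; exact refits for reported R2
  X <- scale(G, center = TRUE, scale = FALSE)
  r <- y - mean(y)
  tss <- sum(r^2)
  if (tss == 0) return(empty)
  rss <- tss
  site_ids <- colnames(G)
  selected <- integer(0)
  steps <- NULL
  adj_cur <- 0
  repeat {
    k <- length(selected)
    df_res <- n - k - 2L
    if (df_res < 1L || k >= m || k >= max_steps) break
    xx <- colSums(X^2)
    xr <- as.numeric(crossprod(X, r))
    ssr <- ifelse(xx > 1e-10, xr^2 / xx, 0)
    ssr[selected] <- -Inf
    best <- which(ssr == max(ssr))[1]  # candidates are in genomic order
    rss_new <- rss - ssr[best]
    F_p <- ssr[best] / (rss_new / df_res)
    p_part <- pf(F_p, 1, df_res, lower.tail = FALSE)
    r2_new <- 1 - rss_new / tss
    adj_new <- 1 - (rss_new / df_res) / (tss / (n - 1))
    if (stop_rule == "adjusted_r2" && adj_new <= adj_cur) break
    if (stop_rule == "partial_f" && p_part > alpha_stop) break
    selected <- c(selected, best)
    ## exact least squares on the chosen sites for the reported R2
    fit <- lm.fit(cbind(1, G[, selected, drop = FALSE]), y)
    rss <- sum(fit$residuals^2)
    r2_new <- 1 - rss / tss
    adj_new <- 1 - (rss / (n - length(selected) - 1L)) / (tss / (n - 1))
    steps <- rbind(steps,
                   data.frame(step = length(selected),
                              site_id = site_ids[best],
                              partial_p = p_part, r2 = r2_new,
                              adj_r2 = adj_new, stringsAsFactors = FALSE))
    adj_cur <- adj_new
    ## orthogonalize the pool and residual against the chosen column
    v <- X[, best]
    nv <- sum(v^2)
    if (nv > 1e-10) {
      u <- v / sqrt(nv)
      X <- X - u %*% crossprod(u, X)
      r <- r - u * sum(u * r)
    }
  }
  out <- list(steps = if (is.null(steps)) empty$steps else steps,
              selected = if (is.null(steps)) character(0) else steps$site_id,
              r2 = if (is.null(steps)) 0 else tail(steps$r2, 1),
              adj_r2 = if (is.null(steps)) 0 else tail(steps$adj_r2, 1),
              n_lines = n)
  class(out) <- "sleepqg_multisnp"
  out
}

#' @export
print.sleepqg_multisnp <- function(x, ...) {
  cat("Forward-selection multi-SNP model:", length(x$selected), "sites,",
      sprintf("R2 = %.3f (adj %.3f), %d lines\n", x$r2, x$adj_r2, x$n_lines))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}

#' Fraction of the genetic variance explained by a multi-SNP model
#'
#' The model R2 is a fraction of phenotypic variance; dividing by the
#' trait's broad-sense heritability converts it to a fraction of genetic
#' variance.  Values above 1 (possible by sampling error) are capped with
#' a warning.
#'
#' @param r2_adj Adjusted R2 of the fitted model.
#' @param h2 Broad-sense heritability of the trait for the same sex.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' genetic_variance_explained(0.27, 0.54)  # 0.5
genetic_variance_explained <- function(r2_adj, h2) {
  if (is.na(h2) || h2 <= 0) stop("h2 must be > 0")
  frac <- r2_adj / h2
  if (frac > 1) {
    warning("R2_adj exceeds H2; fraction capped at 1")
    frac <- 1
  }
  max(frac, 0)
}
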
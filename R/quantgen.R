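#' Partition phenotypic variance with the panel's mixed ANOVA model
#'
#' Fits, by REML (via lme4), the observational model
#' `Y = mu + B + S + L(B) + SxL(B) + R(B) + SxR(B) + RxL(B) + SxRxL(B) + e`
#' with sex fixed and all block/line/replicate terms random; lines are
#' nested in blocks by construction of the line labels.  For per-sex fits
#' the sex terms are dropped (`Y = mu + B + L(B) + R(B) + RxL(B) + e`).
#' When the table has exactly one observation per line x sex x replicate
#' cell (a CV_E table), the replicate-by-line strata are inseparable from
#' the residual and are dropped automatically.
#'
#' Component significance, when requested, is a REML likelihood-ratio test
#' of the model with the component deleted, with the 0.5*(chi2_0 + chi2_1)
#' boundary correction.
#'
#' @param phenos data.frame with columns `line`, `sex`, `block`, `rep`,
#'   `value` (one trait; a `trait` column, if present, must be constant).
#' @param mode `"pooled"`, `"male"` or `"female"`.
#' @param tests Compute per-component likelihood-ratio p-values (one refit
#'   per component; costly on large tables).
#' @return Object of class `sleepqg_varcomp`: list with `components` (named
#'   variances), `p` (named LRT p-values or NULL), `mode`, `scale`
#'   (`"mean"` or `"cve"`, by cell-size detection), `nobs`.
#' @export
fit_variance_model <- function(phenos, mode = c("pooled", "male", "female"),
                               tests = FALSE) {
  mode <- match.arg(mode)
  if (!is.null(phenos$trait) && length(unique(phenos$trait)) > 1L)
    stop("phenos must contain a single trait")
  d <- phenos
  if (mode != "pooled")
    d <- d[d$sex == ifelse(mode == "male", "M", "F"), , drop = FALSE]
  if (length(unique(d$line)) < 2L || length(unique(d$rep)) < 2L)
    stop("singular design: need >= 2 lines and >= 2 replicates")
  if (mode == "pooled" && length(unique(d$sex)) < 2L)
    stop("pooled fit requires both sexes")
  d$line <- factor(d$line); d$block <- factor(d$block)
  d$rep <- factor(d$rep); d$sex <- factor(d$sex)
  cell_n <- data.table::as.data.table(d)[, .N,
                                         by = c("line", "sex", "rep")]$N
  cve_scale <- max(cell_n) == 1L

  if (mode == "pooled") {
    terms <- c(block = "(1 | block)", line = "(1 | line)",
               `sex:line` = "(1 | sex:line)",
               `rep:block` = "(1 | block:rep)",
               `sex:rep:block` = "(1 | sex:block:rep)")
    if (!cve_scale)
      terms <- c(terms, `rep:line` = "(1 | line:rep)",
                 `sex:rep:line` = "(1 | sex:line:rep)")
    fixed <- "value ~ sex"
  } else {
    terms <- c(block = "(1 | block)", line = "(1 | line)",
               `rep:block` = "(1 | block:rep)")
    if (!cve_scale) terms <- c(terms, `rep:line` = "(1 | line:rep)")
    fixed <- "value ~ 1"
  }
  ## a single block is confounded with the grand mean
  if (nlevels(d$block) < 2L) terms <- terms[names(terms) != "block"]
  form <- as.formula(paste(fixed, "+", paste(terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(rhobeg = 0.2, rhoend = 1e-12),
                            check.nobs.vs.nlev = "ignore",
                            check.nobs.vs.rankZ = "ignore",
                            check.conv.singular = "ignore",
                            check.conv.grad = "ignore",
                            calc.derivs = FALSE)
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(form, data = d, REML = TRUE, control = ctrl)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  comp <- setNames(vc$vcov[match(c("block", "line", "sex:line", "block:rep",
                                   "sex:block:rep", "line:rep",
                                   "sex:line:rep"), vc$grp)],
                   c("block", "line", "sex:line", "rep:block",
                     "sex:rep:block", "rep:line", "sex:rep:line"))
  comp <- comp[!is.na(comp)]
  comp["residual"] <- vc$vcov[vc$grp == "Residual"]

  pvals <- NULL
  if (tests) {
    ll_full <- as.numeric(stats::logLik(fit))
    pvals <- setNames(rep(NA_real_, length(terms)), names(terms))
    for (tm in names(terms)) {
      f0 <- as.formula(paste(fixed, "+",
                             paste(terms[names(terms) != tm],
                                   collapse = " + ")))
      fit0 <- if (length(terms) > 1L)
        suppressWarnings(suppressMessages(
          lme4::lmer(f0, data = d, REML = TRUE, control = ctrl)))
      else lm(as.formula(fixed), data = d)
      lrt <- max(0, 2 * (ll_full - as.numeric(stats::logLik(fit0))))
      pvals[tm] <- 0.5 * (1 - pchisq(lrt, df = 1))  # chi-bar-squared mix
    }
  }
  structure(list(components = comp, p = pvals, mode = mode,
                 scale = if (cve_scale) "cve" else "mean",
                 trait = if (!is.null(d$trait)) as.character(d$trait[1])
                 else NA_character_,
                 nobs = nrow(d)),
            class = "sleepqg_varcomp")
}

#' @export
print.sleepqg_varcomp <- function(x, ...) {
  cat("Variance components (", x$mode, ", ", x$scale, " scale, n = ",
      x$nobs, ")\n", sep = "")
  tab <- data.frame(variance = x$components)
  if (!is.null(x$p)) tab$p_lrt <- x$p[rownames(tab)]
  print(tab)
  invisible(x)
}

#' ANOVA (expected-mean-squares) variance components on balanced data
#'
#' Independent method-of-moments cross-check for [fit_variance_model()] on
#' balanced designs, where REML and ANOVA estimators coincide when all
#' estimates are interior.  Mean squares are computed from sequential
#' orthogonal projections; the EMS coefficient matrix is obtained exactly as
#' `tr(P_i Z_j Z_j') / df_i` and the linear system solved for the variance
#' components (estimates may be negative, unlike REML).
#'
#' @inheritParams fit_variance_model
#' @return Named numeric vector of variance-component estimates on the same
#'   terms as [fit_variance_model()].
#' @export
ems_variance_components <- function(phenos, mode = c("pooled", "male",
                                                     "female")) {
  mode <- match.arg(mode)
  d <- phenos
  if (mode != "pooled")
    d <- d[d$sex == ifelse(mode == "male", "M", "F"), , drop = FALSE]
  d$line <- factor(d$line); d$block <- factor(d$block)
  d$rep <- factor(d$rep); d$sex <- factor(d$sex)
  cell_n <- data.table::as.data.table(d)[, .N,
                                         by = c("line", "sex", "rep")]$N
  cve_scale <- max(cell_n) == 1L
  y <- d$value
  n <- length(y)

  ind <- function(f) {
    m <- matrix(0, n, nlevels(f))
    m[cbind(seq_len(n), as.integer(f))] <- 1
    m
  }
  fB <- d$block
  fL <- d$line
  fR <- interaction(d$block, d$rep, drop = TRUE)
  fRL <- interaction(d$line, d$rep, drop = TRUE)
  if (mode == "pooled") {
    fS <- d$sex
    fSL <- interaction(d$sex, d$line, drop = TRUE)
    fSR <- interaction(d$sex, fR, drop = TRUE)
    fSRL <- interaction(d$sex, fRL, drop = TRUE)
    fixed_terms <- list(mu = matrix(1, n, 1), sex = ind(fS))
    rand_terms <- list(block = ind(fB), line = ind(fL),
                       `sex:line` = ind(fSL), `rep:block` = ind(fR),
                       `sex:rep:block` = ind(fSR))
    if (nlevels(fB) < 2L) rand_terms$block <- NULL
    if (!cve_scale)
      rand_terms <- c(rand_terms, list(`rep:line` = ind(fRL),
                                       `sex:rep:line` = ind(fSRL)))
    ## hierarchical fitting order (each term adjusted for those before it)
    order_names <- c("mu", "block", "sex", "line", "sex:line", "rep:block",
                     "sex:rep:block",
                     if (!cve_scale) c("rep:line", "sex:rep:line"))
  } else {
    fixed_terms <- list(mu = matrix(1, n, 1))
    rand_terms <- list(block = ind(fB), line = ind(fL),
                       `rep:block` = ind(fR))
    if (!cve_scale) rand_terms <- c(rand_terms, list(`rep:line` = ind(fRL)))
    if (nlevels(fB) < 2L) rand_terms$block <- NULL
    order_names <- c("mu", "block", "line", "rep:block",
                     if (!cve_scale) "rep:line")
  }
  order_names <- intersect(order_names,
                           c(names(fixed_terms), names(rand_terms)))
  all_terms <- c(fixed_terms, rand_terms)[order_names]

  ## sequential projections: P(term k) spans term k adjusted for 1..k-1
  X <- NULL
  P_prev <- matrix(0, n, n)
  proj <- list()
  dfs <- numeric(0)
  for (nm in order_names) {
    X <- cbind(X, all_terms[[nm]])
    qr_x <- qr(X)
    Q <- qr.Q(qr_x)[, seq_len(qr_x$rank), drop = FALSE]
    P_cur <- tcrossprod(Q)
    proj[[nm]] <- P_cur - P_prev
    dfs[nm] <- sum(diag(proj[[nm]]))
    P_prev <- P_cur
  }
  proj[["residual"]] <- diag(n) - P_prev
  dfs["residual"] <- n - sum(dfs)

  rand_names <- c(names(rand_terms), "residual")
  ZZt <- lapply(rand_terms, tcrossprod)
  ZZt[["residual"]] <- diag(n)
  C <- matrix(0, length(rand_names), length(rand_names),
              dimnames = list(rand_names, rand_names))
  ms <- numeric(length(rand_names)); names(ms) <- rand_names
  for (i in rand_names) {
    ms[i] <- as.numeric(t(y) %*% proj[[i]] %*% y) / dfs[i]
    for (j in rand_names)
      C[i, j] <- sum(proj[[i]] * ZZt[[j]]) / dfs[i]
  }
  solve(C, ms)
}

#' Broad-sense heritability from variance components
#'
#' Pooled-sex: `H2 = (s2_L + s2_SL) / (s2_L + s2_SL + s2_E)` where `s2_E`
#' is the sum of all other variance components (block, replicate strata and
#' residual).  Per-sex fits: `H2 = s2_L / (s2_L + s2_E)`.  Negative
#' component estimates are truncated at zero inside the ratio only.
#'
#' @param vc A `sleepqg_varcomp` from [fit_variance_model()] (or a named
#'   numeric vector on the same terms).
#' @return H2 in `[0, 1]` (NA if the denominator is zero).
#' @export
heritability <- function(vc) {
  comp <- if (inherits(vc, "sleepqg_varcomp")) vc$components else vc
  comp <- pmax(comp, 0)
  gen_terms <- intersect(c("line", "sex:line"), names(comp))
  if (!"line" %in% names(comp)) stop("no line component in vc")
  g <- sum(comp[gen_terms])
  e <- sum(comp[setdiff(names(comp), gen_terms)])
  if (g + e <= 0) return(NA_real_)
  g / (g + e)
}

#' Cross-sex genetic correlation
#'
#' `r_MF = s2_L(pooled) / sqrt(s2_LM x s2_LF)`: the pooled-sex among-line
#' component is the cross-sex genetic covariance in this design.  The
#' reported value is clipped to `[-1, 1]`; the raw ratio is kept in
#' attribute `raw`.
#'
#' @param vc_pooled,vc_m,vc_f `sleepqg_varcomp` fits of the same trait and
#'   scale in pooled, male and female mode.
#' @return r_MF (NA when either per-sex line variance is zero).
#' @export
cross_sex_rg <- function(vc_pooled, vc_m, vc_f) {
  stopifnot(vc_pooled$mode == "pooled", vc_m$mode == "male",
            vc_f$mode == "female")
  num <- vc_pooled$components[["line"]]
  vm <- vc_m$components[["line"]]; vf <- vc_f$components[["line"]]
  if (vm <= 0 || vf <= 0) return(NA_real_)
  raw <- num / sqrt(vm * vf)
  structure(max(-1, min(1, raw)), raw = raw)
}

#' Genetic correlation between two traits from line means
#'
#' Product-moment correlation of sex-averaged line means:
#' `r_G = cov12 / sqrt(s2_L1 x s2_L2)` with all three product moments taken
#' across lines.
#'
#' @param line_means_1,line_means_2 data.frames with `line` and `value`
#'   columns (e.g. from [line_means()]); matched on common lines.
#' @return r_G (NA with fewer than 3 common lines or a zero variance).
#' @export
trait_rg <- function(line_means_1, line_means_2) {
  m <- merge(line_means_1[, c("line", "value")],
             line_means_2[, c("line", "value")], by = "line")
  if (nrow(m) < 3L) return(NA_real_)
  if (sd(m$value.x) == 0 || sd(m$value.y) == 0) return(NA_real_)
  cor(m$value.x, m$value.y)
}

#' Line x sex means and sex-averaged line means
#'
#' @param phenos Long phenotype table (single trait).
#' @return For `line_sex_means`: data.frame `line`, `sex`, `value`.  For
#'   `line_means`: data.frame `line`, `value` (average of the two sex
#'   means, or the single available sex).
#' @export
line_sex_means <- function(phenos) {
  dt <- data.table::as.data.table(phenos)
  as.data.frame(dt[, list(value = mean(value)), by = c("line", "sex")])
}

#' @rdname line_sex_means
#' @export
line_means <- function(phenos) {
  lsm <- line_sex_means(phenos)
  dt <- data.table::as.data.table(lsm)
  as.data.frame(dt[, list(value = mean(value)), by = "line"])
}

#' Test and correct line means for endosymbiont infection effects
#'
#' Tests infection status with a mixed ANOVA on line x sex means
#' (`Y = mu + I + S + IxS + L(I) + e`, infection tested over the
#' line-within-infection stratum) and with per-sex one-way ANOVAs on line
#' means.  For each sex whose test is significant at `alpha`, that sex's
#' line means are centered within infection class (class mean replaced by
#' the grand mean), which preserves the grand mean exactly; otherwise the
#' means are returned unchanged.
#'
#' @param lsm Line x sex means ([line_sex_means()]).
#' @param infection data.frame with `line` and `infected` ("y"/"n").
#' @param alpha Significance level for applying the correction.
#' @return List: `adjusted` (line x sex means after correction), `report`
#'   (p-values and which sexes were corrected).
#' @export
wolbachia_adjust <- function(lsm, infection, alpha = 0.05) {
  d <- merge(lsm, infection[, c("line", "infected")], by = "line")
  if (nrow(d) < nrow(lsm)) stop("infection status missing for some lines")
  if (length(unique(d$infected)) < 2L) {
    return(list(adjusted = lsm,
                report = data.frame(test = "skipped", p = NA_real_,
                                    corrected = FALSE)))
  }
  d$infected <- factor(d$infected); d$sex <- factor(d$sex)
  d$line <- factor(d$line)
  fit <- aov(value ~ infected * sex + Error(line), data = d)
  s <- summary(fit)
  p_overall <- tryCatch(s[["Error: line"]][[1]]["infected", "Pr(>F)"],
                        error = function(e) NA_real_)
  p_int <- tryCatch(s[["Error: Within"]][[1]]["infected:sex", "Pr(>F)"],
                    error = function(e) NA_real_)
  out <- lsm
  report <- data.frame(test = c("overall", "interaction"),
                       p = c(p_overall, p_int), corrected = FALSE,
                       stringsAsFactors = FALSE)
  for (sx in levels(d$sex)) {
    ds <- d[d$sex == sx, ]
    p_s <- anova(lm(value ~ infected, data = ds))["infected", "Pr(>F)"]
    corrected <- !is.na(p_s) && p_s < alpha
    report <- rbind(report, data.frame(test = paste0("sex_", sx), p = p_s,
                                       corrected = corrected))
    if (corrected) {
      grand <- mean(ds$value)
      cls_mean <- tapply(ds$value, ds$infected, mean)
      idx <- out$sex == sx
      inf_of <- d$infected[match(paste(out$line[idx], sx),
                                 paste(d$line, d$sex))]
      out$value[idx] <- out$value[idx] - cls_mean[inf_of] + grand
    }
  }
  list(adjusted = out, report = report)
}

#' Block-effect check on the isogenic control line
#'
#' Fits `Y = mu + B + S + BxS + R(B) + SxR(B) + e` to the control-line fly
#' table and reports F-tests for the block terms with their proper
#' denominators: B over R(B), BxS over SxR(B), and the replicate strata
#' over the residual.  Non-significant block terms indicate that block
#' differences in the panel reflect line sampling, not shared environment.
#'
#' @param control Control-line fly table (`sex`, `block`, `rep`, `value`).
#' @return data.frame: `term`, `df1`, `df2`, `F`, `p`.
#' @export
control_block_check <- function(control) {
  d <- control
  if (length(unique(d$block)) < 2L)
    stop("control line must be measured in more than one block")
  d$block <- factor(d$block); d$sex <- factor(d$sex)
  ## explicit interaction factors keep the sequential fitting order right
  ## (an order-2 term would be reordered after the replicate factors)
  d$blocksex <- interaction(d$block, d$sex, drop = TRUE)
  d$repb <- interaction(d$block, d$rep, drop = TRUE)
  d$sexrepb <- interaction(d$sex, d$repb, drop = TRUE)
  a <- anova(lm(value ~ block + sex + blocksex + repb + sexrepb, data = d))
  ms <- a[, "Mean Sq"]; df <- a[, "Df"]
  names(ms) <- names(df) <- rownames(a)
  ftab <- function(num, den) {
    f <- ms[num] / ms[den]
    data.frame(term = num, df1 = df[num], df2 = df[den], F = unname(f),
               p = unname(pf(f, df[num], df[den], lower.tail = FALSE)))
  }
  out <- rbind(ftab("block", "repb"),
               ftab("blocksex", "sexrepb"),
               ftab("repb", "Residuals"),
               ftab("sexrepb", "Residuals"))
  out$term <- c("block", "block:sex", "rep(block)", "sex:rep(block)")
  rownames(out) <- NULL
  out
}
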
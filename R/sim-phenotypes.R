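#' Simulate per-fly phenotypes under the panel's observational model
#'
#' Runs the variance-partitioning model forward: each fly's value is
#' `mu + block + sex + causal SNP effects (optionally sex-scaled) +
#' polygenic line effect + sex-by-line + replicate terms + residual`, with
#' the residual standard deviation per line equal to `exp(log sigma_E)`
#' where log sigma_E carries its own genetic component (variance-QTL effects
#' plus a polygenic term correlated `rho_mean_sigmaE` with the polygenic
#' mean).  Lines are nested in blocks (each line belongs to exactly one
#' block).  Causal-site variance is counted inside the `var_line` /
#' `var_sexline` / `var_log_sigma_e` targets; the polygenic components make
#' up the remainder, so the targets are the total planted components.
#'
#' @param geno A `sleepqg_genotypes` object from [simulate_genotypes()].
#' @param cfg The [sim_config()] used to generate `geno`.
#' @param trait Trait label written into the output table.
#' @return A list with
#'   \describe{
#'     \item{phenos}{data.frame, one row per fly: `fly_id`, `line`, `sex`
#'       ("M"/"F"), `block`, `rep`, `trait`, `value`.}
#'     \item{truth}{ground-truth record: causal mean/variance sites with
#'       their effects, per-line genetic values, and the planted variance
#'       components.}
#'   }
#' @export
simulate_phenotypes <- function(geno, cfg, trait = "night_sleep") {
  validate_sim_config(cfg)
  stopifnot(inherits(geno, "sleepqg_genotypes"))
  if (nrow(geno$geno) != cfg$n_lines)
    stop("genotype matrix and config disagree on the number of lines")
  set.seed(sub_seed(cfg, "phenotypes"))
  n <- cfg$n_lines
  lb <- line_block_map(cfg)

  sigma_p <- sqrt(cfg$var_line + cfg$var_sexline + cfg$var_block +
                    cfg$var_rep + cfg$var_sexrep + cfg$var_repline +
                    cfg$var_sexrepline + cfg$var_env_mean)

  ## --- causal sites -------------------------------------------------------
  n_c <- min(cfg$n_causal_mean, ncol(geno$geno))
  n_v <- min(cfg$n_causal_var, max(0L, ncol(geno$geno) - n_c))
  pick <- sample.int(ncol(geno$geno), n_c + n_v)
  mean_sites <- head(pick, n_c)
  var_sites <- tail(pick, n_v)

  es <- cfg$effect_sizes_mean
  if (is.data.frame(es)) {
    stopifnot(all(c("es", "mult_m", "mult_f") %in% names(es)))
    es <- es[rep_len(seq_len(nrow(es)), max(n_c, 1L)), , drop = FALSE]
  } else {
    es <- data.frame(es = rep_len(es, max(n_c, 1L)), mult_m = 1, mult_f = 1)
  }
  causal_mean <- NULL
  g_mean_m <- g_mean_f <- numeric(n)
  var_line_causal <- var_sexline_causal <- 0
  if (n_c > 0L) {
    a_m <- es$es[seq_len(n_c)] * sigma_p * es$mult_m[seq_len(n_c)]
    a_f <- es$es[seq_len(n_c)] * sigma_p * es$mult_f[seq_len(n_c)]
    G <- geno$geno[, mean_sites, drop = FALSE]
    q <- colMeans(G)
    ## class means differ by 2a, so the per-line shift is 2a * g
    g_mean_m <- as.numeric(G %*% (2 * a_m))
    g_mean_f <- as.numeric(G %*% (2 * a_f))
    pq <- q * (1 - q)
    var_line_causal <- sum(4 * a_m * a_f * pq)
    var_sexline_causal <- sum(2 * (a_m - a_f)^2 * pq)
    causal_mean <- data.frame(site_id = colnames(G), a_m = a_m, a_f = a_f,
                              alt_freq = q, stringsAsFactors = FALSE)
  }
  causal_var <- NULL
  g_logsig <- numeric(n)
  var_logsig_causal <- 0
  logsig_scale_terms <- 0
  if (n_v > 0L) {
    mult <- rep_len(cfg$effect_sizes_var, n_v)
    Gv <- geno$geno[, var_sites, drop = FALSE]
    qv <- colMeans(Gv)
    g_logsig <- as.numeric(Gv %*% log(mult))
    var_logsig_causal <- sum(log(mult)^2 * qv * (1 - qv))
    logsig_scale_terms <- sum(log((1 - qv) + qv * mult^2))
    causal_var <- data.frame(site_id = colnames(Gv), sigma_mult = mult,
                             alt_freq = qv, stringsAsFactors = FALSE)
  }

  ## --- polygenic line-level draws (bivariate mean / log sigma_E) ----------
  v_mean_poly <- max(0, cfg$var_line - var_line_causal)
  v_logsig_poly <- max(0, cfg$var_log_sigma_e - var_logsig_causal)
  rho <- cfg$rho_mean_sigmaE
  z1 <- rnorm(n); z2 <- rnorm(n)
  poly_mean <- sqrt(v_mean_poly) * z1
  poly_logsig <- sqrt(v_logsig_poly) * (rho * z1 + sqrt(1 - rho^2) * z2)
  ## intercept of log sigma_E so that E[sigma_E^2] = var_env_mean
  m0 <- 0.5 * (log(cfg$var_env_mean) - 2 * v_logsig_poly - logsig_scale_terms)
  log_sigma_e <- m0 + poly_logsig + g_logsig
  v_sl_poly <- max(0, cfg$var_sexline - var_sexline_causal)

  ## --- design-level draws -------------------------------------------------
  blocks <- sprintf("b%d", seq_len(cfg$n_blocks))
  reps <- seq_len(cfg$n_reps_per_block)
  blk_eff <- setNames(rnorm(cfg$n_blocks, 0, sqrt(cfg$var_block)), blocks)
  rep_key <- as.vector(outer(blocks, reps, paste, sep = ".r"))
  rep_eff <- setNames(rnorm(length(rep_key), 0, sqrt(cfg$var_rep)), rep_key)
  sexrep_key <- as.vector(outer(rep_key, c("M", "F"), paste, sep = "."))
  sexrep_eff <- setNames(rnorm(length(sexrep_key), 0, sqrt(cfg$var_sexrep)),
                         sexrep_key)
  sexline_eff <- matrix(rnorm(2 * n, 0, sqrt(v_sl_poly)), n, 2,
                        dimnames = list(lb$line, c("M", "F")))
  repline_eff <- matrix(rnorm(n * cfg$n_reps_per_block, 0,
                              sqrt(cfg$var_repline)),
                        n, cfg$n_reps_per_block, dimnames = list(lb$line, NULL))
  sexrepline_eff <- array(rnorm(n * cfg$n_reps_per_block * 2, 0,
                                sqrt(cfg$var_sexrepline)),
                          dim = c(n, cfg$n_reps_per_block, 2),
                          dimnames = list(lb$line, NULL, c("M", "F")))

  ## --- assemble the fly table ---------------------------------------------
  tab <- expand.grid(fly = seq_len(cfg$flies_per_sex_per_rep),
                     sex = c("M", "F"), rep = reps, line = lb$line,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$block <- lb$block[match(tab$line, lb$line)]
  li <- match(tab$line, lb$line)
  si <- ifelse(tab$sex == "M", 1L, 2L)
  sex_fix <- ifelse(tab$sex == "M", cfg$sex_effect / 2, -cfg$sex_effect / 2)
  g_sex <- ifelse(tab$sex == "M", g_mean_m[li], g_mean_f[li])
  value <- cfg$mu + sex_fix +
    blk_eff[tab$block] +
    rep_eff[paste0(tab$block, ".r", tab$rep)] +
    sexrep_eff[paste0(tab$block, ".r", tab$rep, ".", tab$sex)] +
    poly_mean[li] + g_sex +
    sexline_eff[cbind(li, si)] +
    repline_eff[cbind(li, tab$rep)] +
    sexrepline_eff[cbind(li, tab$rep, si)] +
    rnorm(nrow(tab), 0, exp(log_sigma_e)[li])
  phenos <- data.frame(
    fly_id = sprintf("%s_%s_r%d_f%d", tab$line, tab$sex, tab$rep, tab$fly),
    line = tab$line, sex = tab$sex, block = tab$block, rep = tab$rep,
    trait = trait, value = as.numeric(value), stringsAsFactors = FALSE)

  truth <- list(
    trait = trait,
    causal_mean = causal_mean,
    causal_var = causal_var,
    line_truth = data.frame(line = lb$line, block = lb$block,
                            g_mean = poly_mean + (g_mean_m + g_mean_f) / 2,
                            log_sigma_e = log_sigma_e,
                            stringsAsFactors = FALSE),
    components = list(var_line = cfg$var_line, var_sexline = cfg$var_sexline,
                      var_block = cfg$var_block, var_rep = cfg$var_rep,
                      var_sexrep = cfg$var_sexrep,
                      var_repline = cfg$var_repline,
                      var_sexrepline = cfg$var_sexrepline,
                      var_env_mean = cfg$var_env_mean,
                      var_log_sigma_e = cfg$var_log_sigma_e),
    sigma_p = sigma_p)
  list(phenos = phenos, truth = truth)
}

#' Simulate per-line endosymbiont infection status
#'
#' Bernoulli infection flags per line, with an optional planted additive
#' shift for infected lines (possibly sex-specific) to exercise
#' [wolbachia_adjust()].
#'
#' @param cfg A [sim_config()].
#' @param shift_m,shift_f Additive shift of infected-line phenotypes per sex
#'   (applied by the caller; returned here as metadata).
#' @return data.frame with `line`, `infected` ("y"/"n"), `shift_m`, `shift_f`.
#' @export
simulate_wolbachia <- function(cfg, shift_m = 0, shift_f = 0) {
  set.seed(sub_seed(cfg, "wolbachia"))
  inf <- runif(cfg$n_lines) < cfg$wolbachia_prob
  ## both classes must be represented for the infection model to be testable
  if (all(inf)) inf[1] <- FALSE
  if (!any(inf)) inf[1] <- TRUE
  data.frame(line = line_ids(cfg), infected = ifelse(inf, "y", "n"),
             shift_m = shift_m, shift_f = shift_f, stringsAsFactors = FALSE)
}

#' Simulate the control line measured in every block
#'
#' The isogenic control line has no line-level genetic terms; its flies are
#' `mu + block + sex + rep(block) + sex:rep(block) + residual`.  Planted
#' block effects (for power checks of [control_block_check()]) can be given
#' explicitly.
#'
#' @param cfg A [sim_config()].
#' @param block_effects Optional numeric vector of length `n_blocks` of
#'   fixed block shifts; defaults to random `N(0, var_block)` draws.
#' @return data.frame with `fly_id`, `sex`, `block`, `rep`, `value`.
#' @export
simulate_control <- function(cfg, block_effects = NULL) {
  validate_sim_config(cfg)
  set.seed(sub_seed(cfg, "control"))
  blocks <- sprintf("b%d", seq_len(cfg$n_blocks))
  reps <- seq_len(cfg$n_reps_per_block)
  if (is.null(block_effects))
    block_effects <- rnorm(cfg$n_blocks, 0, sqrt(cfg$var_block))
  blk <- setNames(block_effects, blocks)
  rep_key <- as.vector(outer(blocks, reps, paste, sep = ".r"))
  rep_eff <- setNames(rnorm(length(rep_key), 0, sqrt(cfg$var_rep)), rep_key)
  sexrep_key <- as.vector(outer(rep_key, c("M", "F"), paste, sep = "."))
  sexrep_eff <- setNames(rnorm(length(sexrep_key), 0, sqrt(cfg$var_sexrep)),
                         sexrep_key)
  tab <- expand.grid(fly = seq_len(cfg$flies_per_sex_per_rep),
                     sex = c("M", "F"), rep = reps, block = blocks,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sex_fix <- ifelse(tab$sex == "M", cfg$sex_effect / 2, -cfg$sex_effect / 2)
  value <- cfg$mu + sex_fix + blk[tab$block] +
    rep_eff[paste0(tab$block, ".r", tab$rep)] +
    sexrep_eff[paste0(tab$block, ".r", tab$rep, ".", tab$sex)] +
    rnorm(nrow(tab), 0, sqrt(cfg$var_env_mean))
  data.frame(fly_id = sprintf("ctrl_%s_%s_r%d_f%d", tab$block, tab$sex,
                              tab$rep, tab$fly),
             sex = tab$sex, block = tab$block, rep = tab$rep,
             value = as.numeric(value), stringsAsFactors = FALSE)
}
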
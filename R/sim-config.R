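#' Simulation configuration for a synthetic inbred-line sleep panel
#'
#' Builds the single configuration object consumed by all generators
#' ([simulate_genotypes()], [simulate_phenotypes()], [simulate_activity()]).
#' Defaults describe the measurement design of a DGRP-style reference panel:
#' 168 fully inbred lines split into 4 blocks, phenotyped in 4 replicates per
#' block with 8 flies per sex per replicate (32 flies/sex/line), under a
#' 12 h light : 12 h dark cycle for 7 days.
#'
#' Variance-component defaults are a night-sleep design point: in minutes,
#' `var_line = 4800`, `var_sexline = 600` and environmental terms summing to
#' 4600 give a pooled broad-sense heritability of exactly
#' (4800 + 600) / 10000 = 0.54.  Genetic variance in the residual standard
#' deviation is planted on the log scale (`var_log_sigma_e`), with a
#' line-level correlation `rho_mean_sigmaE` between the genetic mean and
#' log sigma_E (default -0.8, i.e. short-sleeping lines are the most
#' environmentally sensitive).
#'
#' @param n_lines Number of inbred lines.
#' @param n_blocks Number of disjoint line blocks; `n_lines` must be a
#'   multiple of `n_blocks`.
#' @param n_reps_per_block Replicate measurements per block.
#' @param flies_per_sex_per_rep Flies of each sex measured per replicate.
#' @param n_snps Number of simulated biallelic sites.
#' @param sfs_shape Exponent of the power-law distribution of minor-line
#'   counts, `P(k) ~ k^-sfs_shape` over `k = 4 .. floor(n_lines/2)`.  The
#'   default 2.9 places roughly 80\% of sites at minor allele frequency
#'   <= 0.05 (for 168 lines, minor-line count <= 8).
#' @param n_causal_mean Number of sites with planted effects on the trait
#'   mean.
#' @param n_causal_var Number of sites with planted multiplicative effects on
#'   the residual standard deviation (variance-QTLs).
#' @param effect_sizes_mean Standardized mean effects `a / sigma_P`, recycled
#'   over causal sites (`a` is half the difference between homozygous marker
#'   classes).  Alternatively a data.frame with columns `es`, `mult_m`,
#'   `mult_f` giving per-sex multipliers (e.g. `mult_f = 0` for a male-only
#'   effect).
#' @param effect_sizes_var Multiplicative sigma_E effects of the minor allele
#'   at variance-QTLs, recycled.
#' @param mu Grand trait mean (minutes for duration traits).
#' @param sex_effect Fixed male minus female difference.
#' @param var_line,var_sexline Target among-line and sex-by-line variance
#'   components (causal-site variance is counted inside these targets; the
#'   polygenic part makes up the remainder).
#' @param var_block,var_rep,var_sexrep,var_repline,var_sexrepline Variance of
#'   block, replicate-in-block, sex-by-replicate, replicate-by-line and
#'   sex-by-replicate-by-line effects.
#' @param var_env_mean Mean residual (within line-sex-replicate) variance.
#' @param var_log_sigma_e Line-level genetic variance of log sigma_E
#'   (variance-QTL variance counts toward this target).
#' @param rho_mean_sigmaE Correlation between the polygenic line mean and
#'   polygenic log sigma_E.
#' @param ld_block_spec `data.frame(arm, span, n_snps, copy_fidelity)`; each
#'   row plants one local-LD block whose member sites are copies of a
#'   template column with per-line flip probability `1 - copy_fidelity`.
#' @param inversion_spec `data.frame(name, arm, start, end, carrier_fraction)`
#'   describing segregating inversions; sites inside an inversion interval
#'   track the karyotype with fidelity `inversion_fidelity`.
#' @param inversion_fidelity Per-line copy fidelity of in-inversion sites to
#'   the karyotype vector.
#' @param markov_rates Per-phase sleep/wake transition probabilities per
#'   minute: `list(night = c(p_sleep, p_wake), day = c(p_sleep, p_wake))`
#'   where `p_sleep` is P(wake to sleep) and `p_wake` is P(sleep to wake).
#' @param activity_lambda Poisson rate of extra beam crossings per awake
#'   minute (awake minutes carry `1 + Poisson(activity_lambda)` counts).
#' @param dead_fraction Fraction of flies whose record is truncated by death
#'   (all-zero suffix of at least 24 h).
#' @param n_days Days of recording.
#' @param wolbachia_prob Probability that a line carries the endosymbiont
#'   infection (used by [simulate_wolbachia()]).
#' @param seed Integer seed; all generator sub-streams are derived from it by
#'   fixed offsets, so equal configs reproduce identical outputs.
#'
#' @return An object of class `sleepqg_sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_lines = 24, n_snps = 50, seed = 1)
#' geno <- simulate_genotypes(cfg)
#' dim(geno$geno)
sim_config <- function(n_lines = 168L,
                       n_blocks = 4L,
                       n_reps_per_block = 4L,
                       flies_per_sex_per_rep = 8L,
                       n_snps = 1000L,
                       sfs_shape = 2.9,
                       n_causal_mean = 10L,
                       n_causal_var = 5L,
                       effect_sizes_mean = c(0.3, 0.5, 0.7),
                       effect_sizes_var = c(1.25, 1.5),
                       mu = 500,
                       sex_effect = -20,
                       var_line = 4800,
                       var_sexline = 600,
                       var_block = 25,
                       var_rep = 60,
                       var_sexrep = 40,
                       var_repline = 120,
                       var_sexrepline = 80,
                       var_env_mean = 4275,
                       var_log_sigma_e = 0.09,
                       rho_mean_sigmaE = -0.8,
                       ld_block_spec = NULL,
                       inversion_spec = NULL,
                       inversion_fidelity = 0.9,
                       markov_rates = list(night = c(p_sleep = 0.122, p_wake = 0.025),
                                           day   = c(p_sleep = 0.036, p_wake = 0.050)),
                       activity_lambda = 1.0,
                       dead_fraction = 0.0,
                       n_days = 7L,
                       wolbachia_prob = 0.5,
                       seed = 1L) {
  cfg <- list(n_lines = as.integer(n_lines), n_blocks = as.integer(n_blocks),
              n_reps_per_block = as.integer(n_reps_per_block),
              flies_per_sex_per_rep = as.integer(flies_per_sex_per_rep),
              n_snps = as.integer(n_snps), sfs_shape = sfs_shape,
              n_causal_mean = as.integer(n_causal_mean),
              n_causal_var = as.integer(n_causal_var),
              effect_sizes_mean = effect_sizes_mean,
              effect_sizes_var = effect_sizes_var,
              mu = mu, sex_effect = sex_effect,
              var_line = var_line, var_sexline = var_sexline,
              var_block = var_block, var_rep = var_rep,
              var_sexrep = var_sexrep, var_repline = var_repline,
              var_sexrepline = var_sexrepline,
              var_env_mean = var_env_mean,
              var_log_sigma_e = var_log_sigma_e,
              rho_mean_sigmaE = rho_mean_sigmaE,
              ld_block_spec = ld_block_spec,
              inversion_spec = inversion_spec,
              inversion_fidelity = inversion_fidelity,
              markov_rates = markov_rates,
              activity_lambda = activity_lambda,
              dead_fraction = dead_fraction,
              n_days = as.integer(n_days),
              wolbachia_prob = wolbachia_prob,
              seed = as.integer(seed))
  class(cfg) <- "sleepqg_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sleepqg_sim_config"))
  if (cfg$n_lines < 8L) stop("n_lines must be >= 8")
  if (cfg$n_snps < 1L) stop("n_snps must be >= 1")
  if (cfg$n_lines %% cfg$n_blocks != 0L)
    stop("n_lines must be a multiple of n_blocks")
  if (floor(cfg$n_lines / 2) < 4L)
    stop("n_lines too small to host a minor allele in >= 4 lines")
  vars <- c("var_line", "var_sexline", "var_block", "var_rep", "var_sexrep",
            "var_repline", "var_sexrepline", "var_env_mean",
            "var_log_sigma_e")
  for (v in vars) if (cfg[[v]] < 0) stop(v, " must be >= 0")
  if (abs(cfg$rho_mean_sigmaE) > 1) stop("rho_mean_sigmaE must be in [-1, 1]")
  for (ph in c("night", "day")) {
    r <- cfg$markov_rates[[ph]]
    if (is.null(r) || length(r) != 2L)
      stop("markov_rates must have night and day entries of length 2")
    if (any(r < 0) || any(r > 1))
      stop("markov transition probabilities must lie in [0, 1]")
  }
  if (cfg$dead_fraction < 0 || cfg$dead_fraction > 1)
    stop("dead_fraction must be in [0, 1]")
  if (!is.null(cfg$ld_block_spec)) {
    lb <- cfg$ld_block_spec
    stopifnot(is.data.frame(lb),
              all(c("arm", "span", "n_snps", "copy_fidelity") %in% names(lb)))
    if (any(lb$copy_fidelity < 0 | lb$copy_fidelity > 1))
      stop("copy_fidelity must lie in [0, 1]")
  }
  if (!is.null(cfg$inversion_spec)) {
    iv <- cfg$inversion_spec
    stopifnot(is.data.frame(iv),
              all(c("name", "arm", "start", "end", "carrier_fraction")
                  %in% names(iv)))
    if (any(iv$end <= iv$start)) stop("inversion end must exceed start")
    if (any(iv$carrier_fraction <= 0 | iv$carrier_fraction >= 1))
      stop("carrier_fraction must lie in (0, 1)")
  }
  invisible(cfg)
}

## Derived sub-seeds: one global seed, fixed offsets per stream (kept well
## below .Machine$integer.max for any plausible user seed).
sub_seed <- function(cfg, stream) {
  offs <- c(genotypes = 11L, phenotypes = 23L, activity = 37L,
            wolbachia = 53L, control = 71L, karyotype = 89L)
  if (!stream %in% names(offs)) stop("unknown seed stream: ", stream)
  (cfg$seed %% 2000000000L) + offs[[stream]]
}

## Line, block and replicate labels shared by all generators.
line_ids <- function(cfg) sprintf("line_%03d", seq_len(cfg$n_lines))

line_block_map <- function(cfg) {
  per <- cfg$n_lines / cfg$n_blocks
  data.frame(line = line_ids(cfg),
             block = rep(sprintf("b%d", seq_len(cfg$n_blocks)), each = per),
             stringsAsFactors = FALSE)
}
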
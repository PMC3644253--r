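make_lsm <- function(n_lines, f = function(i) rnorm(n_lines)) {
  lines <- sprintf("l%02d", seq_len(n_lines))
  data.frame(line = rep(lines, 2), sex = rep(c("M", "F"), each = n_lines),
             value = c(f(1), f(2)), stringsAsFactors = FALSE)
}

test_that("filter_snps enforces minor-line and coverage bounds exactly", {
  cfg <- quick_cfg(seed = 2)
  g <- simulate_genotypes(cfg)
  ## force specific edge cases into the metadata/matrix
  g$sites$cov[1] <- 30L; g$sites$cov[2] <- 29L; g$sites$cov[3] <- 3L
  g$sites$cov[4] <- 2L
  g$geno[, 5] <- 0L; g$geno[1:3, 5] <- 1L       # minor in 3 lines
  g$geno[, 6] <- 0L; g$geno[1:4, 6] <- 1L       # minor in 4 lines
  f <- filter_snps(g)
  expect_false(g$sites$site_id[1] %in% f$sites$site_id)  # cov 30 out
  expect_true(g$sites$site_id[2] %in% f$sites$site_id)   # cov 29 in
  expect_true(g$sites$site_id[3] %in% f$sites$site_id)   # cov 3 in
  expect_false(g$sites$site_id[4] %in% f$sites$site_id)  # cov 2 out
  expect_false(g$sites$site_id[5] %in% f$sites$site_id)  # 3 minor lines
  expect_true(g$sites$site_id[6] %in% f$sites$site_id)
  ## brute-force per-site re-check on random matrices
  for (s in 1:5) {
    set.seed(600 + s)
    gg <- g
    gg$geno <- matrix(rbinom(length(g$geno), 1, 0.12), nrow(g$geno))
    rownames(gg$geno) <- rownames(g$geno)
    colnames(gg$geno) <- colnames(g$geno)
    gg$sites$cov <- sample(1:35, nrow(gg$sites), replace = TRUE)
    keep_oracle <- vapply(seq_len(ncol(gg$geno)), function(j) {
      k <- sum(gg$geno[, j]); mk <- min(k, nrow(gg$geno) - k)
      mk >= 4 && gg$sites$cov[j] > 2 && gg$sites$cov[j] < 30
    }, TRUE)
    expect_setequal(filter_snps(gg)$sites$site_id,
                    gg$sites$site_id[keep_oracle])
  }
})

test_that("pooled SNP test agrees with the aov split-plot oracle", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(c(12, 20, 31), 1)
    lsm <- make_lsm(n)
    g <- setNames(integer(n), unique(lsm$line))
    g[sample.int(n, sample(4:(n %/% 2), 1))] <- 1L
    mine <- test_snp_pooled(lsm, g)
    orac <- oracle_snp_pooled(lsm, g)
    expect_equal(mine$p_pooled, orac$p_pooled, tolerance = 1e-10)
    expect_equal(mine$p_interaction, orac$p_interaction, tolerance = 1e-10)
  }
})

test_that("constant phenotype gives p in the 1 region", {
  lsm <- make_lsm(12, function(i) rep(5, 12))
  g <- setNames(c(rep(0L, 6), rep(1L, 6)), unique(lsm$line))
  res <- test_snp_pooled(lsm, g)
  expect_true(res$p_pooled > 0.99 || is.na(res$F_pooled))
})

test_that("sex-antagonistic effects load on the interaction term", {
  n_int_small <- 0
  for (s in 1:20) {
    set.seed(700 + s)
    n <- 40
    lines <- sprintf("l%02d", 1:n)
    g <- setNames(rep(0:1, each = n / 2), lines)
    a <- 1.2
    lsm <- data.frame(line = rep(lines, 2),
                      sex = rep(c("M", "F"), each = n),
                      value = c(2 * a * g + rnorm(n),
                                -2 * a * g + rnorm(n)))
    res <- test_snp_pooled(lsm, g)
    if (res$p_interaction < 0.01 && res$p_pooled > 0.05)
      n_int_small <- n_int_small + 1
  }
  expect_gte(n_int_small, 16)
})

test_that("per-sex test matches t-distribution and permutation oracle", {
  ## 3 within-class SDs apart, 10 + 10 lines -> strongly significant
  set.seed(5)
  lines <- sprintf("l%02d", 1:20)
  g <- setNames(rep(0:1, each = 10), lines)
  means <- data.frame(line = lines, value = rnorm(20) + 3 * g)
  expect_lt(test_snp_sex(means, g)$p, 0.01)
  ## permutation oracle within Monte-Carlo error
  for (s in 1:5) {
    set.seed(800 + s)
    means$value <- rnorm(20) + 0.8 * g
    p_mine <- test_snp_sex(means, g)$p
    f_obs <- test_snp_sex(means, g)$F
    perm <- replicate(4000, {
      gp <- setNames(sample(g), lines)
      test_snp_sex(means, gp)$F
    })
    p_perm <- mean(perm >= f_obs)
    expect_lt(abs(p_mine - p_perm), 4 * sqrt(p_mine * (1 - p_mine) / 4000)
              + 0.01)
  }
})

test_that("BH step-up: hand enumeration, edge cases, monotonicity", {
  p <- c(0.001, 0.02, 0.03, 0.9)
  res <- bh_fdr(p, fdr = 0.05)
  expect_equal(sum(res$q <= 0.05), oracle_bh_rejections(p, 0.05))
  expect_equal(sum(res$q <= 0.05), 3L)
  expect_equal(sum(bh_fdr(rep(1, 50))$significant), 0L)
  set.seed(2)
  pr <- runif(200)^2
  q <- bh_fdr(pr)$q
  expect_true(all(diff(q[order(pr)]) >= -1e-12))
  expect_true(all(q >= pr))
  expect_length(bh_fdr(numeric(0))$q, 0L)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  ## random lists against the hand step-up, several alphas
  for (s in 1:20) {
    set.seed(900 + s)
    pr <- runif(sample(5:80, 1))^sample(1:3, 1)
    alpha <- sample(c(0.01, 0.05, 0.1), 1)
    expect_equal(sum(bh_fdr(pr, alpha)$significant),
                 oracle_bh_rejections(pr, alpha))
  }
})

test_that("effect size and V_G arithmetic", {
  e <- effect_and_variance(520, 480, p = 0.5, q = 0.5, sigma_p = 100)
  expect_equal(e$a, 20)
  expect_equal(e$a_over_sigmaP, 0.2)
  expect_equal(effect_and_variance(1, -1, 0.5, 0.5, 1)$V_G, 1)
  ## minimum panel MAF: 4/168 lines
  e2 <- effect_and_variance(0.5, -0.5, p = 0.976, q = 0.024, sigma_p = 1)
  expect_equal(e2$V_G, 4 * 0.976 * 0.024 * 0.25)
  expect_error(effect_and_variance(1, 0, 0.5, 0.5, 0), "sigma_p")
})

test_that("sex-effect classes follow their definitions", {
  expect_equal(classify_sex_effect(0.005, 0.5, 1, 1, 0.5), "specific")
  expect_equal(classify_sex_effect(0.005, 0.008, 0.6, -0.6, 0.001),
               "antagonistic")
  expect_equal(classify_sex_effect(0.005, 0.008, 0.6, 0.3, 0.01), "biased")
  expect_equal(classify_sex_effect(0.005, 0.008, 0.6, 0.55, 0.8), "equal")
  expect_true(is.na(classify_sex_effect(0.5, 0.5, 1, 1, 0.5)))
})

test_that("planted male-only effects classify as specific or male-biased", {
  hits <- 0; total <- 0
  for (s in 1:10) {
    cfg <- sim_config(n_lines = 100, n_blocks = 2, n_reps_per_block = 2,
                      flies_per_sex_per_rep = 8, n_snps = 80,
                      n_causal_mean = 3, n_causal_var = 0,
                      effect_sizes_mean = data.frame(es = 0.8, mult_m = 1,
                                                     mult_f = 0),
                      var_line = 100, var_sexline = 50, var_block = 0,
                      var_rep = 10, var_sexrep = 10, var_repline = 10,
                      var_sexrepline = 10, var_env_mean = 400,
                      var_log_sigma_e = 0, seed = 1000 + s)
    g <- simulate_genotypes(cfg)
    ph <- simulate_phenotypes(g, cfg)
    assoc <- gwa_trait(filter_snps(g), ph$phenos)
    planted <- assoc[assoc$site_id %in% ph$truth$causal_mean$site_id, ]
    detected <- planted[!is.na(planted$sex_class), ]
    total <- total + nrow(detected)
    hits <- hits + sum(detected$sex_class %in% c("specific", "biased") &
                         abs(detected$a_m) > abs(detected$a_f))
  }
  expect_gt(total, 5)
  expect_gte(hits / total, 0.9)
})

test_that("gwa_trait output satisfies its invariants", {
  cfg <- sim_config(n_lines = 60, n_blocks = 2, n_reps_per_block = 2,
                    flies_per_sex_per_rep = 4, n_snps = 120,
                    n_causal_mean = 2, effect_sizes_mean = 0.7, seed = 77)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  assoc <- gwa_trait(filter_snps(g), ph$phenos)
  expect_true(all(assoc$V_G >= 0))
  expect_true(all(assoc$q_pooled >= assoc$p_pooled - 1e-12))
  expect_true(all(is.na(assoc$sex_class) |
                    (assoc$q_m <= 0.01 | assoc$q_f <= 0.01)))
  qq <- qq_table(assoc$p_pooled)
  expect_equal(nrow(qq), nrow(assoc))
  expect_true(all(diff(qq$expected) <= 0) || all(diff(qq$expected) >= 0))
})
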
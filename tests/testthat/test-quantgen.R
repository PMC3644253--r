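balanced_cfg <- function(seed, n_blocks = 2, var_block = 100) {
  sim_config(n_lines = 12, n_blocks = n_blocks, n_reps_per_block = 3,
             flies_per_sex_per_rep = 4, n_snps = 5, n_causal_mean = 0,
             n_causal_var = 0, var_line = 400, var_sexline = 150,
             var_block = var_block, var_rep = 100, var_sexrep = 90,
             var_repline = 120, var_sexrepline = 80, var_env_mean = 60,
             var_log_sigma_e = 0, seed = seed)
}

test_that("REML equals the EMS oracle where the design is orthogonal", {
  ## per-sex reduced model: orthogonal block structure for any block count
  hits <- 0
  for (s in c(2, 5, 8, 12)) {
    cfg <- balanced_cfg(s)
    ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
    ems <- ems_variance_components(ph$phenos, "male")
    if (any(ems <= 0)) next    # REML truncates at the boundary
    vc <- fit_variance_model(ph$phenos, "male")
    expect_equal(unname(vc$components[names(ems)]), unname(ems),
                 tolerance = 1e-5)
    hits <- hits + 1
  }
  expect_gte(hits, 2)
  ## pooled model on a single block (no S x B hole in the strata)
  cfg1 <- balanced_cfg(4, n_blocks = 1, var_block = 0)
  ph1 <- simulate_phenotypes(simulate_genotypes(cfg1), cfg1)
  ems1 <- ems_variance_components(ph1$phenos, "pooled")
  if (all(ems1 > 0)) {
    vc1 <- fit_variance_model(ph1$phenos, "pooled")
    expect_equal(unname(vc1$components[names(ems1)]), unname(ems1),
                 tolerance = 1e-5)
  }
})

test_that("identical flies give all-zero components", {
  d <- expand.grid(fly = 1:3, sex = c("M", "F"), rep = 1:2,
                   line = sprintf("l%d", 1:4), stringsAsFactors = FALSE)
  d$block <- ifelse(d$line %in% c("l1", "l2"), "b1", "b2")
  d$value <- 500
  vc <- fit_variance_model(d, "pooled")
  expect_true(all(vc$components < 1e-8))
})

test_that("null line variance is called non-significant most of the time", {
  n_sig <- 0
  for (s in 1:30) {
    cfg <- sim_config(n_lines = 16, n_blocks = 2, n_reps_per_block = 2,
                      flies_per_sex_per_rep = 4, n_snps = 5,
                      n_causal_mean = 0, n_causal_var = 0,
                      var_line = 0, var_sexline = 0, var_block = 0,
                      var_rep = 20, var_sexrep = 10, var_repline = 0,
                      var_sexrepline = 0, var_env_mean = 100,
                      var_log_sigma_e = 0, seed = 100 + s)
    ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
    vc <- fit_variance_model(ph$phenos, "pooled", tests = TRUE)
    expect_lt(vc$components[["line"]], 30)
    if (vc$p[["line"]] < 0.05) n_sig <- n_sig + 1
  }
  expect_lte(n_sig, 3)  # >= 90% non-significant under the null
})

test_that("singular designs are rejected with a diagnostic", {
  d <- data.frame(line = "l1", sex = rep(c("M", "F"), 4), block = "b1",
                  rep = 1L, value = rnorm(8))
  expect_error(fit_variance_model(d), "singular")
})

test_that("heritability ratio, truncation and invariances", {
  expect_equal(heritability(c(line = 1, `sex:line` = 0, residual = 1)), 0.5)
  expect_equal(heritability(c(line = 0, `sex:line` = 0, residual = 2)), 0)
  expect_equal(heritability(c(line = 2, `sex:line` = 1, block = -5,
                              residual = 1)), 0.75)  # negative truncated
  cfg <- balanced_cfg(7)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  h0 <- heritability(fit_variance_model(ph$phenos, "pooled"))
  ph_shift <- ph$phenos; ph_shift$value <- ph_shift$value + 1000
  ph_scale <- ph$phenos; ph_scale$value <- ph_scale$value * 3.7
  expect_equal(heritability(fit_variance_model(ph_shift, "pooled")), h0,
               tolerance = 1e-4)
  expect_equal(heritability(fit_variance_model(ph_scale, "pooled")), h0,
               tolerance = 1e-4)
})

test_that("cross-sex genetic correlation hits its limits", {
  ## no sex-by-line variance: male and female line effects identical
  cfg <- sim_config(n_lines = 60, n_blocks = 2, n_reps_per_block = 2,
                    flies_per_sex_per_rep = 8, n_snps = 5,
                    n_causal_mean = 0, n_causal_var = 0,
                    var_line = 800, var_sexline = 0, var_block = 0,
                    var_rep = 10, var_sexrep = 10, var_repline = 10,
                    var_sexrepline = 10, var_env_mean = 100,
                    var_log_sigma_e = 0, seed = 41)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  r1 <- cross_sex_rg(fit_variance_model(ph$phenos, "pooled"),
                     fit_variance_model(ph$phenos, "male"),
                     fit_variance_model(ph$phenos, "female"))
  expect_gt(r1, 0.9)
  ## independent per-sex line effects: pooled line variance near zero
  rs <- vapply(1:8, function(s) {
    cfg <- sim_config(n_lines = 60, n_blocks = 2, n_reps_per_block = 2,
                      flies_per_sex_per_rep = 8, n_snps = 5,
                      n_causal_mean = 0, n_causal_var = 0,
                      var_line = 0, var_sexline = 800, var_block = 0,
                      var_rep = 10, var_sexrep = 10, var_repline = 10,
                      var_sexrepline = 10, var_env_mean = 100,
                      var_log_sigma_e = 0, seed = 200 + s)
    ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
    r <- cross_sex_rg(fit_variance_model(ph$phenos, "pooled"),
                      fit_variance_model(ph$phenos, "male"),
                      fit_variance_model(ph$phenos, "female"))
    if (is.na(r)) 0 else as.numeric(r)
  }, 0.0)
  expect_lt(abs(mean(rs)), 0.15)
})

test_that("trait r_G: identity, independence and mean-CV_E recovery", {
  lm1 <- data.frame(line = sprintf("l%d", 1:30), value = rnorm(30))
  lm2 <- lm1; lm2$value <- 2 * lm1$value
  expect_equal(trait_rg(lm1, lm2), 1)
  set.seed(3)
  rs <- replicate(20, {
    a <- data.frame(line = sprintf("l%d", 1:50), value = rnorm(50))
    b <- data.frame(line = sprintf("l%d", 1:50), value = rnorm(50))
    trait_rg(a, b)
  })
  expect_lt(abs(mean(rs)), 0.1)
  expect_true(is.na(trait_rg(lm1[1:2, ], lm2[1:2, ])))
  ## planted negative mean-sigma_E correlation shows up in mean-vs-CV_E r_G
  cfg <- sim_config(n_lines = 168, n_snps = 10, n_causal_mean = 0,
                    n_causal_var = 0, rho_mean_sigmaE = -0.8, seed = 19)
  ph <- simulate_phenotypes(simulate_genotypes(cfg), cfg)
  r <- trait_rg(line_means(ph$phenos), line_means(cve_table(ph$phenos)))
  expect_lt(r, -0.5)
})

test_that("infection correction adjusts only affected sex, preserves mean", {
  set.seed(8)
  lines <- sprintf("l%02d", 1:40)
  infected <- rep(c("y", "n"), each = 20)
  lsm <- expand.grid(line = lines, sex = c("M", "F"),
                     stringsAsFactors = FALSE)
  lsm$value <- rnorm(80, 100, 5)
  ## plant a male-only infection shift
  delta <- 30
  male_inf <- lsm$sex == "M" & infected[match(lsm$line, lines)] == "y"
  lsm$value[male_inf] <- lsm$value[male_inf] + delta
  res <- wolbachia_adjust(lsm, data.frame(line = lines,
                                          infected = infected))
  rep_m <- res$report[res$report$test == "sex_M", ]
  expect_true(rep_m$corrected)
  adj <- res$adjusted
  m_adj <- adj$value[adj$sex == "M"]
  cls <- infected[match(adj$line[adj$sex == "M"], lines)]
  expect_lt(abs(mean(m_adj[cls == "y"]) - mean(m_adj[cls == "n"])), 1e-8)
  expect_equal(mean(m_adj), mean(lsm$value[lsm$sex == "M"]))  # grand mean
  expect_equal(adj$value[adj$sex == "F"], lsm$value[lsm$sex == "F"])
  ## no planted effect: correction rare under the null
  n_corr <- sum(vapply(1:30, function(s) {
    set.seed(300 + s)
    l0 <- lsm; l0$value <- rnorm(80, 100, 5)
    any(wolbachia_adjust(l0, data.frame(line = lines,
                                        infected = infected))$report$corrected)
  }, TRUE))
  expect_lte(n_corr, 5)
  ## single infection class: skipped
  res1 <- wolbachia_adjust(lsm, data.frame(line = lines, infected = "y"))
  expect_equal(res1$report$test, "skipped")
  expect_equal(res1$adjusted, lsm)
})

test_that("control-line block check: calibration, power, degeneracy", {
  base_cfg <- function(s, vb = 0) {
    sim_config(n_lines = 8, n_blocks = 4, n_reps_per_block = 4,
               flies_per_sex_per_rep = 8, n_snps = 5, n_causal_mean = 0,
               n_causal_var = 0, var_block = vb, var_rep = 20,
               var_sexrep = 10, var_env_mean = 400, var_log_sigma_e = 0,
               seed = s)
  }
  null_sig <- power_sig <- 0
  for (s in 1:50) {
    p_null <- control_block_check(simulate_control(base_cfg(400 + s)))
    if (p_null$p[p_null$term == "block"] < 0.05) null_sig <- null_sig + 1
    ## planted block shift of 1 within-fly SD (sqrt(400) = 20)
    ctrl <- simulate_control(base_cfg(500 + s),
                             block_effects = c(0, 20, 0, 20))
    p_pow <- control_block_check(ctrl)
    if (p_pow$p[p_pow$term == "block"] < 0.05) power_sig <- power_sig + 1
  }
  expect_lte(null_sig, 5)    # >= 90% non-significant under the null
  expect_gte(power_sig, 45)  # >= 90% detected with a 1-SD block shift
  one_block <- simulate_control(sim_config(n_lines = 8, n_blocks = 1,
                                           n_snps = 5, seed = 1))
  expect_error(control_block_check(one_block), "more than one block")
})
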
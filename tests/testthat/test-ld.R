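test_that("r2 limits: identical and complementary columns", {
  g1 <- c(rep(0L, 10), rep(1L, 6))
  G <- cbind(a = g1, b = g1, c = 1L - g1)
  r2 <- pairwise_r2(G)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], 1)   # allele-label swap invariance
  expect_true(isSymmetric(r2))
})

test_that("r2 equals the haplotype-frequency D^2 formula to 1e-12", {
  set.seed(12)
  for (i in 1:300) {
    n <- sample(c(20, 50, 168), 1)
    g1 <- rbinom(n, 1, runif(1, 0.05, 0.5))
    g2 <- if (runif(1) < 0.3) {
      gg <- g1; fl <- runif(n) < 0.1; gg[fl] <- 1L - gg[fl]; gg
    } else rbinom(n, 1, runif(1, 0.05, 0.5))
    if (min(sum(g1), n - sum(g1), sum(g2), n - sum(g2)) == 0) next
    r2 <- pairwise_r2(cbind(g1, g2))[1, 2]
    expect_equal(r2, oracle_r2(g1, g2), tolerance = 1e-12)
  }
})

test_that("block chaining: closure, thresholds and gaps", {
  sites <- data.frame(site_id = sprintf("s%d", 1:4),
                      arm = c("2L", "2L", "2L", "3R"),
                      pos = c(1000, 2000, 3000, 1000))
  g <- c(rep(0L, 12), rep(1L, 6))
  G <- cbind(g, g, g, rbinom(18, 1, 0.4))
  b <- find_ld_blocks(pairwise_r2(G), sites)
  expect_equal(nrow(b), 3L)
  expect_length(unique(b$block_id), 1L)
  ## r2 = 0 everywhere -> no blocks
  set.seed(6)
  G0 <- matrix(0L, 30, 3)
  G0[1:10, 1] <- 1L; G0[11:20, 2] <- 1L; G0[c(1:5, 11:15), 3] <- 1L
  r2z <- pairwise_r2(G0)
  b0 <- find_ld_blocks(r2z, sites[1:3, ], r2_threshold = 0.8)
  expect_equal(nrow(b0), 0L)
  ## max_gap splits distant pairs
  b_gap <- find_ld_blocks(pairwise_r2(G[, 1:3]), sites[1:3, ],
                          max_gap = 1500)
  expect_length(unique(b_gap$block_id), 1L)  # chained through the middle
  b_gap2 <- find_ld_blocks(pairwise_r2(G[, c(1, 3)]),
                           sites[c(1, 3), ], max_gap = 1500)
  expect_equal(nrow(b_gap2), 0L)
})

test_that("planted LD blocks are recovered from the generator", {
  recovered <- total <- 0
  for (s in 1:20) {
    cfg <- sim_config(n_lines = 80, n_blocks = 2, n_snps = 60,
                      n_causal_mean = 0, n_causal_var = 0, seed = 1100 + s,
                      ld_block_spec = data.frame(arm = "2R", span = 5e4,
                                                 n_snps = 6,
                                                 copy_fidelity = 0.95))
    g <- simulate_genotypes(cfg)
    members <- g$sites$site_id[!is.na(g$sites$ld_block)]
    sub <- g$sites[g$sites$site_id %in% members, ]
    r2 <- pairwise_r2(g$geno[, members, drop = FALSE])
    blocks <- find_ld_blocks(r2, sub, r2_threshold = 0.3)
    total <- total + length(members)
    if (nrow(blocks) > 0) {
      main <- names(sort(table(blocks$block_id), decreasing = TRUE))[1]
      recovered <- recovered + sum(blocks$block_id == main)
    }
  }
  expect_gte(recovered / total, 0.9)
})

test_that("inversion model: calibration, power, degenerate inputs", {
  set.seed(9)
  lines <- sprintf("l%02d", 1:40)
  carrier <- setNames(rep(c(TRUE, FALSE), each = 20), lines)
  null_sig <- 0
  for (s in 1:100) {
    lsm <- data.frame(line = rep(lines, 2),
                      sex = rep(c("M", "F"), each = 40),
                      value = rnorm(80))
    p <- test_inversion(carrier, lsm)$p_inv
    if (p < 0.05) null_sig <- null_sig + 1
  }
  expect_lte(null_sig, 12)  # ~5% nominal, binomial slack
  power_sig <- 0
  for (s in 1:50) {
    base <- rnorm(80)
    lsm <- data.frame(line = rep(lines, 2),
                      sex = rep(c("M", "F"), each = 40),
                      value = base + carrier[rep(lines, 2)] * 1.0)
    if (test_inversion(carrier, lsm)$p_inv < 0.01) power_sig <- power_sig + 1
  }
  expect_gte(power_sig, 45)
  ## one karyotype class only: skipped
  all_car <- setNames(rep(TRUE, 40), lines)
  lsm <- data.frame(line = rep(lines, 2), sex = rep(c("M", "F"), each = 40),
                    value = rnorm(80))
  expect_true(is.na(test_inversion(all_car, lsm)$p_inv))
  ## constant phenotype: p in the 1 region
  lsm$value <- 7
  p_const <- test_inversion(carrier, lsm)$p_inv
  expect_true(is.na(p_const) || p_const > 0.99)
})

test_that("proxy collapsing counts and identities", {
  assoc <- data.frame(site_id = sprintf("s%d", 1:12),
                      arm = "2L", pos = 1000 * (1:12),
                      p_pooled = seq(1e-6, 1e-4, length.out = 12),
                      sig = c(rep(TRUE, 10), FALSE, FALSE),
                      inversion = NA_character_,
                      stringsAsFactors = FALSE)
  blocks <- data.frame(block_id = "blk_001",
                       site_id = sprintf("s%d", 1:10),
                       arm = "2L", pos = 1000 * (1:10))
  cp <- collapse_proxies(assoc, blocks)
  expect_equal(cp$n_raw, 10L)
  expect_equal(cp$n_collapsed, 1L)
  expect_equal(cp$proxies$proxy_site, "s1")  # smallest p
  ## no blocks/inversions: identity
  nb <- blocks[0, ]
  cp2 <- collapse_proxies(assoc, nb)
  expect_equal(cp2$n_collapsed, cp2$n_raw)
  ## inversion membership wins over LD blocks
  assoc$inversion[1:4] <- "In_2L_t"
  cp3 <- collapse_proxies(assoc, blocks)
  expect_equal(cp3$n_collapsed, 2L)  # inversion group + rest of the block
  expect_true(all(cp3$n_collapsed <= cp3$n_raw))
  ## restricting to non-associated inversions disables that grouping
  cp4 <- collapse_proxies(assoc, blocks, assoc_inversions = character(0))
  expect_equal(cp4$n_collapsed, 1L)
})
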
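test_that("censoring replaces strictly negative values by 1e-6 only", {
  expect_equal(censor_h2c(c(-0.03, 0.2)), c(1e-6, 0.2))
  expect_equal(censor_h2c(0), 0)        # zero passes through
  x <- c(0.01, 0.5, 1e-9)
  expect_identical(censor_h2c(x), x)    # all-positive input unchanged
})

test_that("resampled null h2c values follow censored Normal(0, SE)", {
  se <- 0.1
  tab <- partition_table(chrom = paste0("c", 1:3), n_snp = c(100, 200, 300),
                         h2c = rep(0, 3), se = rep(se, 3))
  set.seed(1)
  raw <- replicate(34000, resample_null_table(tab, censor = FALSE))
  expect_lt(abs(mean(raw)), 0.002)
  expect_lt(abs(sd(raw) - se), 0.002)

  set.seed(2)
  cen <- replicate(34000, resample_null_table(tab, censor = TRUE))
  expect_lt(abs(mean(cen == 1e-6) - 0.5), 0.01)
  # mean of max(N(0,s), 0) is s/sqrt(2*pi)
  expect_lt(abs(mean(cen) - se / sqrt(2 * pi)), 0.002)

  set.seed(7); a <- resample_null_table(tab)
  set.seed(7); b <- resample_null_table(tab)
  expect_identical(a, b)
})

test_that("resampling rejects tables with non-positive SEs", {
  tab <- fix_table6()
  tab$se[2] <- -1
  expect_error(resample_null_table(tab), "validation error")
})

test_that("adaptive MC estimator identities hold on forced sequences", {
  cfg <- adaptive_mc_config()
  # 34th success on replicate 100: successes on draws 1..33 and draw 100
  queue <- local({
    vals <- rep(0.9, 100); vals[c(1:33, 100)] <- 0.1; i <- 0
    function() { i <<- i + 1; vals[i] }
  })
  r <- adaptive_mc_pvalue(0.5, queue, cfg)
  expect_equal(r$p_hat, 34 / 100)
  expect_equal(r$n_replicates, 100)
  expect_identical(r$stop_reason, "a_reached")
  expect_equal(r$n_successes, 34)

  # 475 replicates, zero successes
  r <- adaptive_mc_pvalue(0.01, function() 0.9, cfg)
  expect_equal(r$p_hat, 1 / 476)
  expect_equal(r$n_replicates, 475)
  expect_identical(r$stop_reason, "b_reached")

  # 33 successes among 475 replicates
  queue <- local({
    vals <- rep(0.9, 475); vals[seq(3, by = 14, length.out = 33)] <- 0.1
    i <- 0
    function() { i <<- i + 1; vals[i] }
  })
  r <- adaptive_mc_pvalue(0.5, queue, cfg)
  expect_equal(r$p_hat, 34 / 476)
  expect_equal(r$n_successes, 33)
  expect_identical(r$stop_reason, "b_reached")

  # ties count as successes (draw equal to p_obs)
  r <- adaptive_mc_pvalue(0.3, function() 0.3, adaptive_mc_config(a = 5, b = 20))
  expect_equal(r$n_replicates, 5)
  expect_equal(r$p_hat, 1)
})

test_that("adaptive MC validates observed and null P values", {
  expect_error(adaptive_mc_pvalue(0, function() 0.5), "validation error")
  expect_error(adaptive_mc_pvalue(1.5, function() 0.5), "validation error")
  expect_error(adaptive_mc_pvalue(0.5, function() -0.1), "validation error")
  expect_error(adaptive_mc_config(a = 100, b = 50), "a < b")
})

test_that("hc_correct is deterministic under a fixed seed", {
  set.seed(5)
  tab <- rand_null_table("chicken28")
  r1 <- hc_correct(tab, adaptive_mc_config(seed = 99))
  r2 <- hc_correct(tab, adaptive_mc_config(seed = 99))
  expect_identical(r1[c("p_hc", "n_replicates", "n_successes", "stop_reason")],
                   r2[c("p_hc", "n_replicates", "n_successes", "stop_reason")])
})

test_that("hc_correct saturates at the resolution floor for strong signal", {
  m <- c(100, 200, 300, 400, 500, 600)
  tab <- partition_table(chrom = paste0("c", 1:6), n_snp = m,
                         h2c = 1e-4 * m + 1e-6, se = rep(1e-4, 6))
  r <- hc_correct(tab, adaptive_mc_config(seed = 3))
  expect_lte(r$p_hc, 34 / 475 + 1e-12)
  expect_gte(r$p_hc, 1 / 476)     # resolution floor
  expect_gt(r$lam_cor, 1)
  # raising b sharpens the floor
  r2 <- hc_correct(tab, adaptive_mc_config(b = 2000, seed = 3))
  expect_lte(r2$p_hc, 34 / 2000 + 1e-12)
})

test_that("H-only nulls center beta at zero; censoring biases it positive", {
  hum_h <- run_null_experiment("human22", 1000, censor = FALSE, seed = 31)
  expect_lt(abs(mean(hum_h$beta)), 4 * sd(hum_h$beta) / sqrt(1000))

  hum_hc <- run_null_experiment("human22", 1000, censor = TRUE, seed = 32)
  chk_hc <- run_null_experiment("chicken28", 1000, censor = TRUE, seed = 33)
  t_hum <- mean(hum_hc$beta) / (sd(hum_hc$beta) / sqrt(1000))
  t_chk <- mean(chk_hc$beta) / (sd(chk_hc$beta) / sqrt(1000))
  expect_gt(t_hum, 5)
  expect_gt(t_chk, 5)
  # the bias is stronger for the chicken genome (many micro-chromosomes);
  # compared on the standardized scale mean(beta)/sd(beta) because raw
  # slopes live in genome-specific size units
  expect_gt(mean(chk_hc$beta) / sd(chk_hc$beta),
            mean(hum_hc$beta) / sd(hum_hc$beta))
})

test_that("null P value distribution is invariant to the SE scale constant", {
  base <- run_null_experiment("chicken28", 400, k = 1, seed = 17)
  up <- run_null_experiment("chicken28", 400, k = 100, seed = 17)
  dn <- run_null_experiment("chicken28", 400, k = 0.01, seed = 17)
  expect_lt(max(abs(base$p - up$p)), 1e-4)
  expect_lt(max(abs(base$p - dn$p)), 1e-4)
  expect_lt(abs(qq_lambda(base$p)$lam / qq_lambda(up$p)$lam - 1), 0.01)
})
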
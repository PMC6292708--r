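test_that("SNP allocation is multinomial by length with a floor of 3", {
  set.seed(1)
  g <- load_genome_preset("human22")
  m <- allocate_snps(g, 10000)
  expect_equal(sum(m), 10000)
  expect_true(all(m >= 3))
  # expected counts track chromosome length
  mm <- rowMeans(replicate(100, allocate_snps(g, 10000)))
  expect_gt(cor(mm, g$size_bp), 0.99)

  # equal-size two-chromosome genome splits evenly (binomial sd ~50)
  g2 <- data.frame(chrom = c("a", "b"), size_bp = c(5e7, 5e7))
  draws <- replicate(50, allocate_snps(g2, 10000))
  expect_lt(max(abs(draws - 5000)), 250)

  # tiny chromosome is raised to 3 SNPs by transfer from the largest
  g3 <- data.frame(chrom = c("big", "mid", "tiny"),
                   size_bp = c(1e8, 1e7, 1e3))
  m3 <- allocate_snps(g3, 12)
  expect_equal(sum(m3), 12)
  expect_gte(m3[3], 3)

  expect_error(allocate_snps(g3, 8), "validation error")
  g1 <- data.frame(chrom = "only", size_bp = 1e6)
  expect_equal(allocate_snps(g1, 50), 50L)
})

test_that("simulated genotypes respect the MAF filter, HWE and the seed", {
  cfg <- sim_config(genome3(), n_i = 500, n_l = 300, seed = 4)
  ds <- simulate_genotypes(cfg)
  expect_equal(dim(ds$genotypes), c(500, 300))
  expect_true(all(ds$genotypes %in% 0:2))
  f <- colMeans(ds$genotypes) / 2
  expect_true(all(pmin(f, 1 - f) >= 0.05))
  expect_equal(sum(ds$snp_counts), 300)
  # per-locus genotype mean is ~2p under HWE (5 sigma bound per locus)
  dev <- abs(colMeans(ds$genotypes) - 2 * ds$freqs)
  bound <- 5 * sqrt(2 * ds$freqs * (1 - ds$freqs) / 500)
  expect_true(all(dev < pmax(bound, 0.08)))

  ds2 <- simulate_genotypes(cfg)
  expect_identical(ds$genotypes, ds2$genotypes)
  expect_identical(ds$freqs, ds2$freqs)
})

test_that("genotype standardization matches its closed form", {
  expect_equal(standardize_genotypes(matrix(0), 0.5)[1, 1], -sqrt(2),
               tolerance = 1e-12)
  expect_equal(standardize_genotypes(matrix(1), 0.5)[1, 1], 0,
               tolerance = 1e-12)
  expect_equal(standardize_genotypes(matrix(2), 0.25)[1, 1],
               1.5 / sqrt(0.375), tolerance = 1e-12)
  expect_error(standardize_genotypes(matrix(1), 0), "validation error")
  expect_error(standardize_genotypes(matrix(1), 1), "validation error")
})

test_that("the GRM is W W'/m with the expected moments", {
  # one SNP, p = 0.5, genotypes (0, 2): off-diagonal (-sqrt2)(sqrt2)/1 = -2
  w <- standardize_genotypes(matrix(c(0, 2), ncol = 1), 0.5)
  A <- compute_grm(w)
  expect_equal(A[1, 2], -2, tolerance = 1e-12)

  # duplicated individuals have equal diagonal and mutual entries
  set.seed(5)
  cfg <- sim_config(genome3(), n_i = 30, n_l = 120, seed = 5)
  ds <- simulate_genotypes(cfg)
  x <- ds$genotypes; x[2, ] <- x[1, ]
  W <- standardize_genotypes(x, ds$freqs)
  A <- compute_grm(W)
  expect_equal(A[1, 1], A[2, 2], tolerance = 1e-12)
  expect_equal(A[1, 2], A[1, 1], tolerance = 1e-12)

  # moment check: mean diagonal ~1, off-diagonal sd ~ 1/sqrt(m)
  cfg <- sim_config(data.frame(chrom = "c", size_bp = 1e6),
                    n_i = 300, n_l = 1000, seed = 6)
  ds <- simulate_genotypes(cfg)
  A <- compute_grm(standardize_genotypes(ds$genotypes, ds$freqs))
  expect_lt(abs(mean(diag(A)) - 1), 0.02)
  off <- A[lower.tri(A)]
  expect_lt(abs(sd(off) * sqrt(1000) - 1), 0.2)
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8 * max(ev))  # PSD
})

test_that("phenotype simulation hits the target heritability", {
  set.seed(8)
  cfg <- sim_config(genome3(), n_i = 1000, n_l = 200, n_causal = 50, h2 = 0.5,
                    seed = 8)
  ds <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(ds, 50, 0.5)
  expect_equal(ph$resid_var, var(ph$genetic_values), tolerance = 1e-12)
  expect_length(ph$causal_idx, 50)

  # near-unit heritability: phenotype ~ genetic value
  ph1 <- simulate_phenotype(ds, 50, 1 - 1e-9)
  expect_lt(max(abs(ph1$y - ph1$genetic_values)), 1e-3)

  # realized h2 within +-0.05 of target across replicates
  real <- replicate(20, simulate_phenotype(ds, 50, 0.5)$realized_h2)
  expect_true(all(abs(real - 0.5) < 0.05))

  # null phenotype carries no genetic signal
  ph0 <- simulate_phenotype(ds, 0, 0)
  expect_identical(ph0$genetic_values, rep(0, 1000))
  expect_error(simulate_phenotype(ds, 50, 1), "validation error")
})

test_that("REML matches a fine grid search of the profile likelihood", {
  set.seed(11)
  grid <- seq(0, 1 - 1e-9, length.out = 2001)
  for (i in 1:20) {
    cfg <- sim_config(data.frame(chrom = "c", size_bp = 1e6),
                      n_i = 40, n_l = 30)
    ds <- simulate_genotypes(cfg)
    A <- compute_grm(standardize_genotypes(ds$genotypes, ds$freqs))
    h2_true <- sample(c(0, 0.3, 0.7), 1)
    y <- if (h2_true == 0) rnorm(40) else simulate_phenotype(ds, 10, h2_true)$y
    fit <- reml_fit(y, A)
    eig <- hcpart:::.grm_eigen(A)
    yt <- drop(crossprod(eig$vectors, y))
    ll_grid <- max(vapply(grid, function(h) {
      hcpart:::.reml_profile(h, eig$d, eig$x2, yt^2, eig$xt * yt, 40)
    }, 0))
    expect_gte(fit$loglik, ll_grid - 1e-6)
    expect_true(fit$converged)
    expect_gt(fit$se, 0)
  }
})

test_that("REML is equivariant under phenotype rescaling", {
  set.seed(12)
  cfg <- sim_config(genome3(), n_i = 80, n_l = 90, n_causal = 20, h2 = 0.4,
                    seed = 12)
  ds <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(ds, 20, 0.4)
  A <- compute_grm(standardize_genotypes(ds$genotypes, ds$freqs))
  f1 <- reml_fit(ph$y, A)
  k <- 3.7
  f2 <- reml_fit(k * ph$y, A)
  expect_equal(f2$h2c, f1$h2c, tolerance = 1e-6)
  expect_equal(f2$sigma2_g, k^2 * f1$sigma2_g, tolerance = 1e-6)
  expect_equal(f2$sigma2_e, k^2 * f1$sigma2_e, tolerance = 1e-6)
  expect_equal(f2$loglik, f1$loglik - (80 - 1) * log(k), tolerance = 1e-6)
})

test_that("REML rejects invalid inputs", {
  expect_error(reml_fit(rep(1, 10), diag(10)), "zero variance")
  expect_error(reml_fit(rnorm(10), diag(9)), "does not match")
  B <- diag(10); B[1, 2] <- B[2, 1] <- 2  # indefinite
  expect_error(reml_fit(rnorm(10), B), "positive semi-definite")
})

test_that("partitioning composes per-chromosome REML fits", {
  cfg <- sim_config(genome3(), n_i = 100, n_l = 150, n_causal = 30, h2 = 0.5,
                    seed = 14)
  ds <- simulate_genotypes(cfg)
  ph <- simulate_phenotype(ds, 30, 0.5)
  tab <- partition_dataset(ds, ph)
  expect_s3_class(tab, "partition_table")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$n_snp, as.numeric(ds$snp_counts))
  for (c in 1:3) {
    idx <- which(ds$chrom_of == c)
    A <- compute_grm(standardize_genotypes(ds$genotypes[, idx, drop = FALSE],
                                           ds$freqs[idx]))
    direct <- reml_fit(ph$y, A)
    expect_equal(tab$h2c[c], direct$h2c, tolerance = 1e-9)
    expect_equal(tab$se[c], direct$se, tolerance = 1e-6)
  }
})

test_that("null datasets pile censored estimates at the boundary", {
  floor_frac <- unlist(lapply(1:3, function(i) {
    cfg <- sim_config("chicken28", n_i = 150, n_l = 600, seed = 20 + i)
    ds <- simulate_genotypes(cfg)
    tab <- partition_dataset(ds, simulate_phenotype(ds, 0, 0))
    tab$h2c == 1e-6
  }))
  expect_true(all(unlist(floor_frac) %in% c(TRUE, FALSE)))
  frac <- mean(floor_frac)
  expect_gt(frac, 0.3)  # roughly half of the fits at the censoring floor
  expect_lt(frac, 0.7)
})

test_that("resample and full modes give matching inflation estimates", {
  full <- run_null_experiment("human22", 120, mode = "full",
                              n_i = 160, n_l = 1600, seed = 21)
  res <- run_null_experiment("human22", 1000, mode = "resample",
                             n_l = 1600, seed = 22)
  lam_f <- qq_lambda(full$p)$lam
  lam_r <- qq_lambda(res$p)$lam
  expect_lt(abs(lam_f / lam_r - 1), 0.25)
})
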
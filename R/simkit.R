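#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data engine: a genome (preset
#' name, [load_genome_preset()] object, or custom `data.frame(chrom,
#' size_bp)`), the number of individuals and SNPs, the genetic
#' architecture (number of causal loci and target narrow-sense
#' heritability), the minor-allele-frequency filter, and a seed.
#'
#' @param genome genome preset name, preset object, or custom size table.
#' @param n_i number of individuals.
#' @param n_l total number of SNPs (at least 3 per chromosome).
#' @param n_causal number of causal loci (0 under the null).
#' @param h2 target narrow-sense heritability in \[0, 1).
#' @param maf_min minimum minor allele frequency (default 0.05).
#' @param seed optional integer seed.
#' @return List of class `"sim_config"`.
#' @export
sim_config <- function(genome, n_i, n_l, n_causal = 0L, h2 = 0,
                       maf_min = 0.05, seed = NULL) {
  genome <- .as_genome(genome)
  n_i <- as.integer(n_i); n_l <- as.integer(n_l); n_causal <- as.integer(n_causal)
  if (n_i < 2) stop("validation error: need n_i >= 2", call. = FALSE)
  if (n_l < 3 * nrow(genome)) {
    stop("validation error: n_l = ", n_l, " too small for ", nrow(genome),
         " chromosomes (need >= 3 SNPs each)", call. = FALSE)
  }
  if (!(h2 >= 0 && h2 < 1)) {
    stop("validation error: h2 must be in [0, 1)", call. = FALSE)
  }
  if (h2 > 0 && n_causal < 1) {
    stop("validation error: h2 > 0 requires n_causal >= 1", call. = FALSE)
  }
  if (n_causal > n_l) {
    stop("validation error: n_causal exceeds n_l", call. = FALSE)
  }
  if (!(maf_min > 0 && maf_min < 0.5)) {
    stop("validation error: maf_min must be in (0, 0.5)", call. = FALSE)
  }
  structure(list(genome = genome, n_i = n_i, n_l = n_l, n_causal = n_causal,
                 h2 = h2, maf_min = maf_min, seed = seed),
            class = "sim_config")
}

#' Allocate SNPs to chromosomes by length
#'
#' SNP counts are drawn multinomially with probabilities proportional to
#' chromosome lengths (SNP placement uniform over the genome). Any
#' chromosome that receives fewer than 3 SNPs has its count raised to 3 by
#' transfer from the largest count, so every per-chromosome model remains
#' identifiable.
#'
#' @param genome a genome preset or custom size table.
#' @param n_l total SNP count.
#' @return Integer vector of per-chromosome SNP counts summing to `n_l`.
#' @export
allocate_snps <- function(genome, n_l) {
  genome <- .as_genome(genome)
  nc <- nrow(genome)
  if (n_l < 3 * nc) {
    stop("validation error: n_l = ", n_l, " < 3 SNPs per chromosome",
         call. = FALSE)
  }
  m <- as.integer(rmultinom(1, n_l, genome$size_bp / sum(genome$size_bp)))
  while (any(m < 3)) {
    i <- which.min(m); j <- which.max(m)
    m[j] <- m[j] - (3L - m[i]); m[i] <- 3L
  }
  m
}

#' Simulate linkage-equilibrium genotypes
#'
#' Per-locus reference allele frequencies are drawn uniformly on
#' (`maf_min`, 1 - `maf_min`) and genotypes as Binomial(2, p) independently
#' across loci and individuals (Hardy-Weinberg, linkage equilibrium). Loci
#' whose empirical minor allele frequency falls below `maf_min` are
#' redrawn. SNPs are assigned to chromosomes via [allocate_snps()].
#'
#' This generator deliberately carries no linkage disequilibrium: all
#' quantities the package studies (GRM sampling noise, the SE-size
#' relation, boundary censoring, P value inflation) are driven by
#' chromosome-size structure and GRM noise, not by LD. See the methods
#' vignette for what this does and does not emulate.
#'
#' @param cfg a [sim_config()]. If `cfg$seed` is set the RNG is seeded.
#' @return Object of class `"genotype_dataset"`: list with `genotypes`
#'   (n_i x n_l integer matrix of allele counts), `freqs` (the generating
#'   allele frequencies), `chrom_of` (per-locus chromosome index),
#'   `snp_counts` (per-chromosome m_c), `chrom` (labels), `maf_min`.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_i; m_tot <- cfg$n_l
  counts <- allocate_snps(cfg$genome, m_tot)
  p <- runif(m_tot, cfg$maf_min, 1 - cfg$maf_min)
  x <- matrix(rbinom(n * m_tot, 2L, rep(p, each = n)), nrow = n)
  repeat {
    f <- colMeans(x) / 2
    bad <- which(pmin(f, 1 - f) < cfg$maf_min)
    if (!length(bad)) break
    p[bad] <- runif(length(bad), cfg$maf_min, 1 - cfg$maf_min)
    x[, bad] <- rbinom(n * length(bad), 2L, rep(p[bad], each = n))
  }
  out <- list(genotypes = x, freqs = p,
              chrom_of = rep(seq_along(counts), counts),
              snp_counts = counts,
              chrom = as.character(cfg$genome$chrom),
              maf_min = cfg$maf_min)
  class(out) <- "genotype_dataset"
  out
}

#' Standardize genotypes to GCTA scale
#'
#' Applies w = (x - 2p) / sqrt(2 p (1 - p)) elementwise, the usual
#' centering and scaling by the binomial standard deviation under
#' Hardy-Weinberg, so each locus has mean ~0 and variance ~1.
#'
#' @param genotypes n x m matrix of allele counts in \{0, 1, 2\}.
#' @param freqs per-locus reference allele frequency in (0, 1).
#' @return Numeric n x m matrix of standardized genotypes.
#' @export
standardize_genotypes <- function(genotypes, freqs) {
  if (any(freqs <= 0 | freqs >= 1)) {
    stop("validation error: allele frequencies must be in (0, 1)", call. = FALSE)
  }
  sweep(sweep(genotypes, 2, 2 * freqs, "-"), 2,
        sqrt(2 * freqs * (1 - freqs)), "/")
}

#' Genomic relationship matrix from standardized genotypes
#'
#' A = W W' / m for the m loci of one chromosome; symmetric positive
#' semi-definite by construction, mean diagonal ~1.
#'
#' @param w n x m matrix of standardized genotypes ([standardize_genotypes()]).
#' @return n x n GRM.
#' @export
compute_grm <- function(w) {
  w <- as.matrix(w)
  if (ncol(w) < 1) stop("validation error: need >= 1 SNP", call. = FALSE)
  tcrossprod(w) / ncol(w)
}

#' Simulate an additive phenotype with a target heritability
#'
#' Causal loci are sampled uniformly without replacement; allelic effects
#' u are standard normal; the genetic value is g = sum(w u) over causal
#' loci on the standardized scale. The residual is Normal(0, sigma2_e)
#' with sigma2_e = var(g) (1/h2 - 1), using the realized sample variance
#' of g, so the realized heritability matches the target up to residual
#' sampling noise. With h2 = 0 the phenotype is standard normal with no
#' association to genotype.
#'
#' @param dataset a [simulate_genotypes()] result.
#' @param n_causal number of causal loci (ignored when `h2 = 0`).
#' @param h2 target narrow-sense heritability in \[0, 1).
#' @return Object of class `"phenotype_sim"`: `y`, `causal_idx`,
#'   `effects`, `genetic_values`, `resid_var`, `realized_h2`.
#' @export
simulate_phenotype <- function(dataset, n_causal, h2) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  if (!(h2 >= 0 && h2 < 1)) {
    stop("validation error: h2 must be in [0, 1)", call. = FALSE)
  }
  n <- nrow(dataset$genotypes)
  if (h2 == 0) {
    out <- list(y = rnorm(n), causal_idx = integer(0), effects = numeric(0),
                genetic_values = rep(0, n), resid_var = 1, realized_h2 = 0)
    class(out) <- "phenotype_sim"
    return(out)
  }
  if (n_causal < 1) {
    stop("validation error: h2 > 0 requires n_causal >= 1", call. = FALSE)
  }
  idx <- sort(sample.int(ncol(dataset$genotypes), n_causal))
  u <- rnorm(n_causal)
  w <- standardize_genotypes(dataset$genotypes[, idx, drop = FALSE],
                             dataset$freqs[idx])
  g <- drop(w %*% u)
  vg <- var(g)
  resid_var <- vg * (1 / h2 - 1)
  y <- g + rnorm(n, 0, sqrt(resid_var))
  out <- list(y = y, causal_idx = idx, effects = u, genetic_values = g,
              resid_var = resid_var, realized_h2 = vg / var(y))
  class(out) <- "phenotype_sim"
  out
}

## ---- REML via spectral decomposition -----------------------------------

# Profile restricted log-likelihood at variance ratio h = sg/(sg+se).
# d: GRM eigenvalues; x2, y2, xy: squared/cross terms of the rotated
# intercept and data vectors; n: sample size.
.reml_profile <- function(h, d, x2, y2, xy, n) {
  w <- h * d + (1 - h)
  sxx <- sum(x2 / w)
  q <- sum(y2 / w) - sum(xy / w)^2 / sxx
  s <- q / (n - 1)
  -0.5 * ((n - 1) * (log(2 * pi) + log(s) + 1) + sum(log(w)) + log(sxx))
}

# Restricted log-likelihood at variance components (sg, se).
.reml_loglik <- function(sg, se, d, x2, y2, xy, n) {
  v <- sg * d + se
  if (any(v <= 0)) return(-Inf)
  sxx <- sum(x2 / v)
  q <- sum(y2 / v) - sum(xy / v)^2 / sxx
  -0.5 * ((n - 1) * log(2 * pi) + sum(log(v)) + log(sxx) + q)
}

# Eigendecomposition wrapper with PSD check; reusable across refits.
.grm_eigen <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) stop("GRM must be square", call. = FALSE)
  eig <- eigen(A, symmetric = TRUE)
  if (min(eig$values) < -1e-8 * max(abs(eig$values))) {
    stop("validation error: GRM is not positive semi-definite", call. = FALSE)
  }
  eig$values[eig$values < 0] <- 0
  xt <- drop(crossprod(eig$vectors, rep(1, nrow(A))))
  list(d = eig$values, vectors = eig$vectors, xt = xt, x2 = xt^2,
       n = nrow(A))
}

#' REML fit of a single-GRM animal model
#'
#' Fits y = mu + g + e with var(g) = sigma2_g A and var(e) = sigma2_e I by
#' restricted maximum likelihood, the model GCTA fits per chromosome with
#' one GRM. The GRM is eigendecomposed once; the restricted likelihood is
#' then profiled over the variance ratio h = sigma2_g / (sigma2_g +
#' sigma2_e) on \[0, 1), located by a coarse grid plus golden-section
#' refinement, with the total variance solved in closed form. The ratio is
#' constrained non-negative (boundary estimates allowed, mimicking GCTA's
#' constrained REML); a boundary estimate is reported as h2c = 1e-6 after
#' censoring.
#'
#' The standard error of h2c comes from the inverse observed information
#' of (sigma2_g, sigma2_e) at the optimum (central finite differences) via
#' the delta method on the ratio; when that is not invertible (degenerate
#' boundary cases) the curvature of the profile likelihood is used instead
#' and flagged in `se_method`.
#'
#' @param y phenotype vector (a `phenotype_sim` is also accepted).
#' @param A symmetric PSD GRM matching `y` in dimension. Alternatively
#'   pass a precomputed decomposition via `eig` (as produced internally;
#'   see [build_grm_cache()]) and leave `A` as `NULL`.
#' @param eig optional precomputed eigendecomposition (overrides `A`).
#' @param compute_se compute the SE of h2c (skip in tight loops that only
#'   need the point estimate).
#' @return Object of class `"reml_fit"`: `sigma2_g`, `sigma2_e`,
#'   `sigma2_p`, `h2c_raw`, `h2c` (censored), `se`, `se_method`,
#'   `loglik`, `converged`, `n`.
#' @export
reml_fit <- function(y, A = NULL, eig = NULL, compute_se = TRUE) {
  if (inherits(y, "phenotype_sim")) y <- y$y
  y <- as.numeric(y)
  if (var(y) <= 0) {
    stop("validation error: phenotype has zero variance", call. = FALSE)
  }
  if (is.null(eig)) {
    if (is.null(A)) stop("supply either A or eig", call. = FALSE)
    eig <- .grm_eigen(A)
  }
  n <- eig$n
  if (length(y) != n) {
    stop("validation error: length(y) does not match GRM dimension",
         call. = FALSE)
  }
  yt <- drop(crossprod(eig$vectors, y))
  .reml_fit_rotated(yt, eig, compute_se = compute_se)
}

# Core fit on already-rotated data; reused across permutation replicates.
.reml_fit_rotated <- function(yt, eig, compute_se = TRUE) {
  n <- eig$n
  d <- eig$d; x2 <- eig$x2; xt <- eig$xt
  y2 <- yt^2; xy <- xt * yt
  hmax <- 1 - 1e-9
  f <- function(h) .reml_profile(h, d, x2, y2, xy, n)
  grid <- seq(0, hmax, length.out = 21)
  lg <- vapply(grid, f, 0)
  converged <- all(is.finite(lg))
  i <- which.max(lg)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(21L, i + 1L)]
  op <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-9)
  h <- op$maximum; ll <- op$objective
  l0 <- f(0)
  if (l0 >= ll) { h <- 0; ll <- l0 }  # boundary wins on ties
  w <- h * d + (1 - h)
  sxx <- sum(x2 / w)
  q <- sum(y2 / w) - sum(xy / w)^2 / sxx
  s <- q / (n - 1)
  sg <- h * s; se2 <- (1 - h) * s
  se_h <- NA_real_; se_method <- "none"
  if (compute_se) {
    hess <- .reml_hessian(sg, se2, d, x2, y2, xy, n, scale = s)
    info <- -hess
    sp <- sg + se2
    if (all(is.finite(info)) && det(info) > 0 && info[1, 1] > 0) {
      vc <- solve(info)
      gr <- c(se2, -sg) / sp^2
      v <- drop(t(gr) %*% vc %*% gr)
      if (is.finite(v) && v > 0) {
        se_h <- sqrt(v); se_method <- "observed_information"
      }
    }
    if (!is.finite(se_h) || se_h <= 0) {
      # profile-curvature fallback at (or near) the boundary
      h0 <- min(max(h, 1e-5), hmax - 1e-5)
      dd <- 1e-5
      l2 <- (f(h0 + dd) - 2 * f(h0) + f(h0 - dd)) / dd^2
      if (is.finite(l2) && l2 < 0) {
        se_h <- 1 / sqrt(-l2); se_method <- "profile_curvature"
      }
    }
    if (!is.finite(se_h) || se_h <= 0) {
      # last resort: half-unit profile-likelihood drop width, the distance
      # above the optimum at which the restricted loglik falls by 0.5
      # (equals 1/sqrt(curvature) for a quadratic profile); always positive
      # and defined even when the profile is flat or convex at the boundary
      drop_fn <- function(hh) (ll - f(hh)) - 0.5
      se_h <- if (drop_fn(hmax) <= 0) hmax - h else {
        stats::uniroot(drop_fn, c(h, hmax), tol = 1e-9)$root - h
      }
      se_h <- max(se_h, 1e-8)
      se_method <- "profile_drop"
    }
  }
  out <- list(sigma2_g = sg, sigma2_e = se2, sigma2_p = sg + se2,
              h2c_raw = h, h2c = if (h <= 0) 1e-6 else h,
              se = se_h, se_method = se_method, loglik = ll,
              converged = converged, n = n)
  class(out) <- "reml_fit"
  out
}

# Central-difference Hessian of the restricted log-likelihood in (sg, se).
.reml_hessian <- function(sg, se2, d, x2, y2, xy, n, scale) {
  g <- function(p) .reml_loglik(p[1], p[2], d, x2, y2, xy, n)
  eps <- 1e-4 * scale
  p0 <- c(sg, se2)
  H <- matrix(0, 2, 2)
  for (a in 1:2) {
    pa <- p0; pb <- p0
    pa[a] <- pa[a] + eps; pb[a] <- pb[a] - eps
    H[a, a] <- (g(pa) - 2 * g(p0) + g(pb)) / eps^2
  }
  pp <- p0 + c(eps, eps); pm <- p0 + c(eps, -eps)
  mp <- p0 + c(-eps, eps); mm <- p0 - c(eps, eps)
  H[1, 2] <- H[2, 1] <- (g(pp) - g(pm) - g(mp) + g(mm)) / (4 * eps^2)
  H
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("Single-GRM REML fit\n")
  cat(sprintf("  sigma2_g = %.4g, sigma2_e = %.4g (n = %d)\n",
              x$sigma2_g, x$sigma2_e, x$n))
  cat(sprintf("  h2c = %.4g (SE %.4g, %s)%s\n", x$h2c, x$se, x$se_method,
              if (x$h2c_raw == 0) " [boundary]" else ""))
  cat(sprintf("  REML loglik = %.4f, converged: %s\n", x$loglik, x$converged))
  invisible(x)
}

#' Precompute per-chromosome GRM eigendecompositions
#'
#' Builds the standardized genotypes, GRM and eigendecomposition for every
#' chromosome of a simulated dataset once, so repeated REML fits (e.g.
#' across permutation replicates) only pay for a rotation of the phenotype
#' and a one-dimensional likelihood search.
#'
#' @param dataset a [simulate_genotypes()] result.
#' @return List of class `"grm_cache"`, one decomposition per chromosome.
#' @export
build_grm_cache <- function(dataset) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  cache <- lapply(seq_along(dataset$snp_counts), function(c) {
    idx <- which(dataset$chrom_of == c)
    w <- standardize_genotypes(dataset$genotypes[, idx, drop = FALSE],
                               dataset$freqs[idx])
    .grm_eigen(compute_grm(w))
  })
  names(cache) <- dataset$chrom
  attr(cache, "snp_counts") <- dataset$snp_counts
  class(cache) <- "grm_cache"
  cache
}

#' Per-chromosome partitioning of a simulated dataset
#'
#' Fits each chromosome's GRM separately against the full phenotype
#' ([reml_fit()] per chromosome) and assembles the censored h2c estimates,
#' their SEs and the SNP counts into a [partition_table] ready for
#' [ols_slope_test()] or [hc_correct()].
#'
#' @param dataset a [simulate_genotypes()] result.
#' @param phenotype a `phenotype_sim` or numeric phenotype vector.
#' @param cache optional [build_grm_cache()] result to reuse.
#' @param compute_se compute per-chromosome SEs (needed for a valid table;
#'   disable only for internal resampling loops).
#' @return A [partition_table] with attributes `fits` (the per-chromosome
#'   `reml_fit` objects) and `converged` (logical vector).
#' @export
partition_dataset <- function(dataset, phenotype, cache = NULL,
                              compute_se = TRUE) {
  stopifnot(inherits(dataset, "genotype_dataset"))
  y <- if (inherits(phenotype, "phenotype_sim")) phenotype$y else as.numeric(phenotype)
  if (is.null(cache)) cache <- build_grm_cache(dataset)
  fits <- lapply(cache, function(e) reml_fit(y, eig = e, compute_se = compute_se))
  tab <- partition_table(
    chrom = dataset$chrom,
    n_snp = dataset$snp_counts,
    h2c = vapply(fits, `[[`, 0, "h2c"),
    se = if (compute_se) vapply(fits, `[[`, 0, "se") else rep(1, length(fits)),
    size_column = "n_snp",
    provenance = "partition_dataset")
  attr(tab, "fits") <- fits
  attr(tab, "converged") <- vapply(fits, `[[`, TRUE, "converged")
  tab
}

#' Null-hypothesis partitioning experiments
#'
#' Generates many datasets under the null hypothesis of no genetic signal
#' and returns the per-dataset one-tailed OLS P value and slope -- the
#' ingredients of the inflation diagnostics ([qq_lambda()], false-positive
#' rates).
#'
#' Two routes produce equivalent distributions:
#' \describe{
#'   \item{`"resample"`}{the fast route: per dataset, SNP counts m_c are
#'     allocated by chromosome length, per-chromosome SEs set to
#'     k sqrt(m_c) (the heteroscedasticity law of REML estimates under
#'     linkage equilibrium), h2c drawn from Normal(0, SE) and censored
#'     (set `censor = FALSE` for the heteroscedasticity-only diagnostic),
#'     then the one-tailed OLS slope test is run on (m_c, h2c).}
#'   \item{`"full"`}{the end-to-end route: genotypes are simulated, a
#'     phenotype with h2 = 0 drawn, every chromosome REML-fitted and the
#'     OLS test run on the resulting table.}
#' }
#'
#' @param genome genome preset name, preset, or custom size table.
#' @param n_datasets number of independent datasets.
#' @param mode `"resample"` (default) or `"full"`.
#' @param n_l total SNPs per dataset.
#' @param n_i individuals per dataset (full mode only).
#' @param k SE scale constant in se_c = k sqrt(m_c) (resample mode only;
#'   the null P value distribution is invariant to k).
#' @param censor apply 1e-6 censoring to the resampled h2c (resample mode).
#' @param maf_min MAF filter (full mode).
#' @param seed master seed; per-dataset streams are derived
#'   deterministically from it.
#' @param store_tables keep each dataset's partition table (full mode;
#'   memory permitting) in attribute `tables`.
#' @return A `data.frame` of class `"null_experiment"` with columns
#'   `dataset`, `p` (one-tailed OLS P) and `beta`, plus attributes `mode`
#'   and `genome_name`.
#' @examples
#' ex <- run_null_experiment("human22", n_datasets = 100, seed = 1)
#' qq_lambda(ex$p)
#' @export
run_null_experiment <- function(genome, n_datasets = 1000,
                                mode = c("resample", "full"),
                                n_l = 10000, n_i = 2000, k = 1,
                                censor = TRUE, maf_min = 0.05,
                                seed = NULL, store_tables = FALSE) {
  mode <- match.arg(mode)
  genome <- .as_genome(genome)
  if (n_datasets < 1) stop("need n_datasets >= 1", call. = FALSE)
  p <- numeric(n_datasets); beta <- numeric(n_datasets)
  tables <- if (store_tables) vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    if (!is.null(seed)) set.seed(.derive_seed(seed, i))
    if (mode == "resample") {
      m <- allocate_snps(genome, n_l)
      se <- k * sqrt(m)
      h <- rnorm(length(m), 0, se)
      if (censor) h <- censor_h2c(h)
      mx <- mean(m); sxx <- sum((m - mx)^2)
      beta[i] <- sum((m - mx) * (h - mean(h))) / sxx
      p[i] <- .ols_p_one(m, h, sxx = sxx, mx = mx)
      if (store_tables) {
        tables[[i]] <- partition_table(chrom = genome$chrom, n_snp = m,
                                       h2c = h, se = se,
                                       provenance = "resample_null")
      }
    } else {
      cfg <- sim_config(genome, n_i = n_i, n_l = n_l, n_causal = 0L,
                        h2 = 0, maf_min = maf_min)
      ds <- simulate_genotypes(cfg)
      ph <- simulate_phenotype(ds, 0L, 0)
      tab <- partition_dataset(ds, ph)
      fit <- ols_slope_test(tab)
      p[i] <- fit$p_one_tailed; beta[i] <- fit$beta
      if (store_tables) tables[[i]] <- tab
    }
  }
  out <- data.frame(dataset = seq_len(n_datasets), p = p, beta = beta)
  attr(out, "mode") <- mode
  attr(out, "genome_name") <- attr(genome, "name")
  if (store_tables) attr(out, "tables") <- tables
  class(out) <- c("null_experiment", "data.frame")
  out
}

#' QQ plot of a null experiment
#'
#' Observed versus expected -log10 P with the 1:1 line and the fitted
#' through-origin inflation slope.
#'
#' @param x a [run_null_experiment()] result.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.null_experiment <- function(x, ...) {
  n <- nrow(x)
  o <- -log10(sort(x$p))
  e <- -log10((seq_len(n) - 0.5) / n)
  lam <- qq_lambda(x$p)$lam
  plot(e, o, xlab = "expected -log10 P", ylab = "observed -log10 P",
       main = sprintf("lambda = %.2f", lam), ...)
  abline(0, 1)
  abline(0, lam, lty = 2)
  invisible(x)
}
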
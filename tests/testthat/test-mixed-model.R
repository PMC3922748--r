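test_that("standardization: reference example, idempotence, degenerate input", {
  ## a C4:0 value of 1.79 with mean 1.53 and SD 0.26 standardizes to 1
  x <- c(1.79, 1.53, 1.27)   # mean 1.53, sd 0.26
  ph <- data.frame(`C4:0` = x, check.names = FALSE)
  std <- standardize_phenotypes(ph, "C4:0")
  expect_equal(std$center[["C4:0"]], 1.53)
  expect_equal(std$scale[["C4:0"]], 0.26)
  expect_equal(unname(std$y[1L, "C4:0"]), 1.00, tolerance = 1e-12)

  ## already standardized data is unchanged
  set.seed(8)
  z <- scale(rnorm(200))[, 1L]
  out <- standardize_phenotypes(data.frame(z = z), "z")
  expect_equal(out$y[, "z"], z, tolerance = 1e-10, ignore_attr = TRUE)

  expect_error(standardize_phenotypes(data.frame(a = rep(2, 10)), "a"),
               "zero-variance.*a")
})

test_that("design matrix: Wilmink pair, reference coding, rank checks", {
  set.seed(4)
  cv <- data.frame(dim = c(0, 100, 150, sample(63:282, 12L)),
                   afc = c(22, 24, 26, rnorm(12, 24, 2)),
                   season = rep(c("S1", "S2", "S3"), 5L),
                   sire_code = sample(c("K1", "K2"), 15L, replace = TRUE),
                   herd = sample(c("H1", "H2"), 15L, replace = TRUE))
  X <- build_design_matrices(cv)
  expect_equal(unname(X[1L, "wilmink"]), 1.0)            # exp(0)
  expect_equal(unname(X[2L, "wilmink"]), exp(-5), tolerance = 1e-12)
  expect_equal(unname(X[2L, "wilmink"]), 6.7379e-3, tolerance = 1e-4)
  expect_equal(sum(startsWith(colnames(X), "season")), 2L)  # 3 seasons
  expect_equal(sum(startsWith(colnames(X), "sire_code")), 1L)
  ## configurable exponent
  X2 <- build_design_matrices(cv, wilmink_exponent = 0.1)
  expect_equal(unname(X2[2L, "wilmink"]), exp(-10), tolerance = 1e-12)

  ## collinear columns are named in the error
  cv_bad <- data.frame(dim = c(10, 20, 30, 40), afc = 24,
                       season = "S1", sire_code = "K1", herd = "H1")
  expect_error(build_design_matrices(cv_bad), "collinear.*afc2")
  expect_error(build_design_matrices(cv[, -1L]), "missing covariate")
})

test_that("latent-factor dimension choice follows the eigenvalue rule", {
  ## perfectly correlated traits: one factor
  y1 <- rnorm(100)
  ph <- data.frame(a = y1, b = 2 * y1 + 1, c = -y1)
  expect_equal(choose_num_factors(ph, traits = c("a", "b", "c")), 1L)

  ## exactly orthogonal columns (identity correlation), t = 10: k = 9
  yo <- stats::poly(1:200, 10)
  colnames(yo) <- paste0("p", 1:10)
  expect_equal(choose_num_factors(as.data.frame(yo), 0.9), 9L)
  expect_equal(choose_num_factors(as.data.frame(yo), 0.35), 4L)

  ## data from a 4-factor model with small noise: k = 4
  set.seed(21)
  f <- matrix(rnorm(4000), 1000, 4)
  L <- matrix(rnorm(40, sd = 1), 4, 10)
  yf <- f %*% L + matrix(rnorm(10000, sd = 0.15), 1000, 10)
  colnames(yf) <- paste0("t", 1:10)
  expect_equal(choose_num_factors(as.data.frame(yf), 0.9), 4L)

  expect_error(choose_num_factors(data.frame(a = rnorm(5)), 0.9),
               "2 traits")
  expect_error(choose_num_factors(ph, 1.5), "threshold")
})

test_that("covariance reconstruction from loadings", {
  expect_equal(reconstruct_covariance(matrix(0, 2, 3), c(1, 2, 3)),
               diag(c(1, 2, 3)))
  got <- reconstruct_covariance(matrix(c(1, 1), 1), c(0.02, 0.02))
  expect_equal(got, rbind(c(1.02, 1.00), c(1.00, 1.02)))
  set.seed(9)
  for (rep in 1:10) {
    k <- sample(1:3, 1L); t <- sample(2:6, 1L)
    S <- reconstruct_covariance(matrix(rnorm(k * t), k), runif(t, 0.1, 2))
    expect_no_error(chol(S))
  }
  expect_error(reconstruct_covariance(matrix(1, 1, 2), c(1, 0)),
               "positive")
})

test_that("the Gibbs sampler is deterministic and validates its run lengths", {
  sim <- mtm_sim(80L, 77L, n_herds = 4L)
  f1 <- fit_mtm(sim$phenotypes, sim$pedigree, k = 1L, chains = 1L,
                iters = 400L, burn_in = 50L, thin = 5L, seed = 5L)
  f2 <- fit_mtm(sim$phenotypes, sim$pedigree, k = 1L, chains = 1L,
                iters = 400L, burn_in = 50L, thin = 5L, seed = 5L)
  expect_identical(f1$samples$R0, f2$samples$R0)
  expect_identical(f1$samples$G0, f2$samples$G0)
  f3 <- fit_mtm(sim$phenotypes, sim$pedigree, k = 1L, chains = 1L,
                iters = 400L, burn_in = 50L, thin = 5L, seed = 6L)
  expect_false(identical(f1$samples$R0, f3$samples$R0))

  expect_error(fit_mtm(sim$phenotypes, sim$pedigree, k = 1L, chains = 1L,
                       iters = 100L, burn_in = 100L, seed = 1L),
               "post-burn-in")
  expect_error(fit_mtm(sim$phenotypes, sim$pedigree, k = 9L, seed = 1L),
               "k must")
  expect_error(fit_mtm(sim$phenotypes, sim$pedigree, k = 1L,
                       variance_floor = 0, seed = 1L), "variance_floor")
})

test_that("every posterior covariance sample is SPD with floored diagonal", {
  fit <- mtm_recovery_fit()
  floor <- fit$config$variance_floor
  arrs <- list(fit$samples$R0, fit$samples$G0)
  for (arr in arrs) {
    S <- dim(arr)[3L]
    for (s in seq(1L, S, by = 7L)) {
      M <- arr[, , s]
      expect_equal(M, t(M), tolerance = 1e-12)
      expect_true(all(diag(M) >= floor - 1e-12))
      expect_no_error(chol(M))
    }
  }
})

test_that("posterior recovers the generating covariances within 3 posterior SDs", {
  sim <- fixture("mtm_recovery_sim", function() mtm_sim(1200L, 31L))
  fit <- mtm_recovery_fit()
  truth <- standardized_truth(sim)
  for (mat in c("R0", "G0")) {
    arr <- fit$samples[[mat]]
    want <- truth[[mat]]
    z <- matrix(NA_real_, 5, 5)
    for (i in 1:5) for (j in i:5) {
      dr <- arr[i, j, ]
      z[i, j] <- abs(mean(dr) - want[i, j]) / stats::sd(dr)
    }
    expect_true(all(z[upper.tri(z, diag = TRUE)] <= 3),
                info = paste(mat, "max z:",
                             round(max(z, na.rm = TRUE), 2)))
  }
})

test_that("implied heritabilities stay inside the admissible band", {
  fit <- mtm_recovery_fit()
  h2 <- implied_heritability(fit)
  ## with both variance components floored at 0.02 and total near 1 on
  ## the standardized scale, h2 cannot escape [0.02, 0.98]
  expect_true(all(h2 >= 0.02 & h2 <= 0.98))
  ## and the point estimates are moderate, as generated
  expect_true(all(colMeans(h2) > 0.1 & colMeans(h2) < 0.75))
})

test_that("posterior mean error shrinks from n = 150 to n = 1200 (k = t - 1)", {
  sim_small <- mtm_sim(150L, 55L, n_herds = 5L)
  fit_small <- fit_mtm(sim_small$phenotypes, sim_small$pedigree, k = 4L,
                       chains = 1L, iters = 3000L, burn_in = 750L,
                       thin = 10L, seed = 17L)
  sim_big <- fixture("mtm_recovery_sim", function() mtm_sim(1200L, 31L))
  fit_big <- fixture("mtm_consistency_fit", function()
    fit_mtm(sim_big$phenotypes, sim_big$pedigree, k = 4L, chains = 1L,
            iters = 3000L, burn_in = 750L, thin = 10L, seed = 17L))
  err <- function(fit, sim) {
    want <- standardized_truth(sim)$R0
    mean(abs(fit$R0_mean - want))
  }
  expect_lt(err(fit_big, sim_big), err(fit_small, sim_small))
})
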
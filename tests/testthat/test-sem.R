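test_that("lambda structures validate pattern, traits and acyclicity", {
  tr <- c("A", "B", "C")
  st <- lambda_structure(tr, data.frame(parent = c("A", "B"),
                                        child = c("B", "C")))
  expect_true(st$free["B", "A"])
  expect_true(st$free["C", "B"])
  expect_equal(sum(st$free), 2L)

  expect_error(lambda_structure(tr, data.frame(parent = "A", child = "Z")),
               "unknown trait")
  expect_error(lambda_structure(tr, data.frame(parent = "A", child = "A")),
               "diagonal")
  expect_error(lambda_structure(tr, data.frame(parent = c("A", "B"),
                                               child = c("B", "A"))),
               "acyclic|cyclic")

  ## TSV round trip
  p <- tempfile(fileext = ".tsv")
  write_lambda_structure(st, p)
  st2 <- read_lambda_structure(p, tr)
  expect_equal(st$free, st2$free)

  ch <- chain_structure(c("x", "y", "z"))
  expect_equal(sum(ch$free), 2L)
  expect_true(ch$free["y", "x"] && ch$free["z", "y"])
})

test_that("reduced-form covariances: identity, 2x2 algebra, round trip", {
  G <- matrix(c(1, 0.3, 0.3, 1), 2)
  out <- reduced_form_covariances(matrix(0, 2, 2), G, c(1, 2))
  expect_equal(out$G0, G)
  expect_equal(out$R0, diag(c(1, 2)))

  L <- rbind(c(0, 0), c(1, 0))
  out2 <- reduced_form_covariances(L, matrix(0, 2, 2), c(1, 1))
  expect_equal(out2$R0, rbind(c(1, 1), c(1, 2)))

  ## round trip: recover Psi0 from the implied residual covariance
  set.seed(31)
  for (rep in 1:10) {
    t <- sample(3:6, 1L)
    L <- matrix(0, t, t)
    L[lower.tri(L)] <- rnorm(t * (t - 1) / 2) *
      (runif(t * (t - 1) / 2) < 0.5)
    psi <- runif(t, 0.2, 2)
    out <- reduced_form_covariances(L, diag(t), psi)
    back <- (diag(t) - L) %*% out$R0 %*% t(diag(t) - L)
    expect_equal(back, diag(psi), tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("DIC: point mass, effective parameter count of a linear model", {
  expect_equal(compute_dic(rep(12.3, 50), 12.3),
               list(dic = 12.3, pd = 0, mean_deviance = 12.3,
                    deviance_at_mean = 12.3))
  expect_error(compute_dic(c(rep(1, 40), NA), 1), "non-finite")
  expect_error(compute_dic(rep(1, 10), 1), "at least 30")

  ## for a fixed-effects-only normal model with known sigma, pD is the
  ## number of regressors (closed-form posterior, no MCMC involved)
  set.seed(41)
  n <- 600L; p <- 8L; sigma <- 1.3
  X <- cbind(1, matrix(rnorm(n * (p - 1L)), n))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, sigma)
  XtXi <- solve(crossprod(X))
  bhat <- drop(XtXi %*% crossprod(X, y))
  ch <- chol(XtXi)
  devs <- replicate(4000L, {
    b <- bhat + sigma * drop(t(ch) %*% rnorm(p))
    sum((y - X %*% b)^2) / sigma^2 + n * log(2 * pi * sigma^2)
  })
  d_at_mean <- sum((y - X %*% bhat)^2) / sigma^2 + n * log(2 * pi * sigma^2)
  dic <- compute_dic(devs, d_at_mean)
  expect_equal(dic$pd, p, tolerance = 0.15)
})

test_that("SEM fitting: empty structure, determinism, degenerate inputs", {
  sim <- mtm_sim(80L, 91L, n_herds = 4L)
  tr <- paste0("T", 1:5)

  ## empty structure: no lambda samples, model is an
  ## independent-residual multi-trait model
  st0 <- lambda_structure(tr)
  f0 <- fit_sem(sim$phenotypes, sim$pedigree, st0, k = 1L, chains = 1L,
                iters = 400L, burn_in = 100L, thin = 5L, seed = 3L)
  expect_equal(ncol(f0$lambda), 0L)
  expect_true(all(f0$psi > 0))

  ## deterministic under (config, seed)
  st <- chain_structure(tr[1:3])
  f1 <- fit_sem(sim$phenotypes, sim$pedigree, st, k = 1L, chains = 1L,
                iters = 400L, burn_in = 100L, thin = 5L, seed = 4L)
  f2 <- fit_sem(sim$phenotypes, sim$pedigree, st, k = 1L, chains = 1L,
                iters = 400L, burn_in = 100L, thin = 5L, seed = 4L)
  expect_identical(f1$lambda, f2$lambda)

  ## a zero-variance parent trait aborts before sampling
  bad <- sim$phenotypes
  bad$T1 <- 1.0
  expect_error(fit_sem(bad, sim$pedigree, st, seed = 1L),
               "zero-variance.*T1")

  expect_error(fit_sem(sim$phenotypes, sim$pedigree,
                       data.frame(parent = "T1", child = "T9"),
                       traits = tr, seed = 1L),
               "unknown trait")
})

test_that("structural coefficients center on the collapsed regression estimate", {
  ## founders, single parent-child pair: the posterior mean of lambda
  ## must agree with the regression of the child on the parent; the
  ## posterior is wider because the correlated-genetic-effects device
  ## admits confounding that plain regression excludes
  set.seed(5)
  n <- 500L
  ped <- parse_pedigree(data.frame(animal = sprintf("C%04d", 1:n),
                                   sire = "0", dam = "0"))
  cv <- data.frame(animal = sprintf("C%04d", 1:n),
                   herd = rep(sprintf("H%02d", 1:10), each = n / 10),
                   dim = sample(63:282, n, TRUE), afc = rnorm(n, 24, 2),
                   season = sample(c("S1", "S2", "S3"), n, TRUE),
                   sire_code = sample(c("K1", "K2"), n, TRUE))
  tr <- simulation_truth(c("A", "B"), rbind(c(0, 0), c(1, 0)),
                         matrix(0, 2, 2), c(1, 0.25),
                         trait_means = c(0, 0), trait_sds = c(1, 1))
  ph <- simulate_phenotypes_from_sem(tr, ped, cv, seed = 9)
  st <- lambda_structure(c("A", "B"), data.frame(parent = "A",
                                                 child = "B"))
  sf <- fit_sem(ph, ped, st, k = 1L, chains = 2L, iters = 6000L,
                burn_in = 1500L, thin = 10L, seed = 11L)
  std <- standardize_phenotypes(ph, c("A", "B"))
  X <- build_design_matrices(cv)
  ols <- stats::lm(std$y[, "B"] ~ std$y[, "A"] + X - 1)
  lam <- sf$lambda[, 1L]
  expect_lt(abs(mean(lam) - coef(ols)[[1L]]), 3 * stats::sd(lam))
  expect_gt(stats::sd(lam), 0.5 * sqrt(stats::vcov(ols)[1L, 1L]))
})

test_that("lambda recovery on the 5-trait chain at n = 2000", {
  sim <- recovery_sim()
  sf <- recovery_sem()
  lam <- structural_coefficients(sf, "original")
  tsd <- sim$truth$trait_sds
  truth_orig <- c(1.05, 0.90, 0.85, 0.95) * tsd[2:5] / tsd[1:4]
  for (j in 1:4) {
    z <- abs(mean(lam[, j]) - truth_orig[j]) / stats::sd(lam[, j])
    expect_lte(z, 3, label = paste("z for", colnames(lam)[j]))
  }
  ## sanity on the reported scale: all chain coefficients on the
  ## standardized-generating scale sit in a plausible positive range
  lam_model <- sweep(lam, 2L, tsd[2:5] / tsd[1:4], "/")
  expect_true(all(colMeans(lam_model) > 0.5 & colMeans(lam_model) < 1.5))
})

test_that("model comparison report and reduced-form identity", {
  sim <- recovery_sim()
  mtm <- fixture("recovery_mtm_chain", function()
    fit_mtm(sim$phenotypes, sim$pedigree, k = 2L, chains = 2L,
            iters = 8000L, burn_in = 2000L, thin = 10L, seed = 3L))
  sem <- recovery_sem()
  cmp <- compare_models(mtm, sem)
  t <- 5L
  expect_equal(nrow(cmp$report), 2L * t + 2L * t * (t - 1L) / 2L)
  expect_equal(cmp$delta_dic, sem$dic$dic - mtm$dic$dic)

  ## SEM generated the data, so it should be better supported
  expect_lt(cmp$delta_dic, 0)
  expect_true(is.finite(cmp$pd_sem) && cmp$pd_sem > 0)
  expect_true(is.finite(cmp$pd_mtm) && cmp$pd_mtm > 0)

  ## conditioning on the parent removes almost all residual variance of
  ## downstream traits (the qualitative signature of the SEM refit)
  res_mtm <- cmp$report$mtm_mean[1:t]
  res_sem <- cmp$report$sem_mean[1:t]
  expect_true(all(res_sem[2:5] < 0.5 * res_mtm[2:5]))

  ## reduced-form identity: the multi-trait fit of SEM-generated data
  ## matches the reduced form of the generating truth (3 posterior SDs)
  rf <- reduced_form_covariances(sim$truth$lambda, sim$truth$G0_star,
                                 sim$truth$Psi0)
  y <- as.matrix(sim$phenotypes[, sim$truth$traits])
  sds <- apply(y, 2L, stats::sd) / sim$truth$trait_sds  # model-scale SDs
  d <- tcrossprod(sds)
  want <- rf$R0 / d
  arr <- mtm$samples$R0
  for (i in 1:5) for (j in i:5) {
    dr <- arr[i, j, ]
    ## the 0.02 variance floor biases near-unity residual correlations
    ## slightly downward, so allow the floor's width on top of 3 SDs
    expect_lt(abs(mean(dr) - want[i, j]),
              3 * stats::sd(dr) + 0.06)
  }

  covs <- c("animal", "herd", "dim", "afc", "season", "sire_code")
  expect_error(compare_models(mtm, fit_sem(
    sim$phenotypes[, c(covs, "C4:0", "C6:0")],
    sim$pedigree, chain_structure(c("C4:0", "C6:0")), k = 1L,
    chains = 1L, iters = 500L, burn_in = 100L, thin = 10L, seed = 2L)),
    "different trait sets")
})

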
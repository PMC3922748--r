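# A generating truth inside the latent-factor model class: R0 and G0 are
# loadings-plus-diagonal with remaining variances well above the 0.02
# floor, so the fitted model is correctly specified.
mtm_truth <- function() {
  r <- rbind(c(0.60, 0.55, 0.50, 0.45, 0.40),
             c(0.10, -0.15, 0.20, -0.10, 0.15))
  s <- rbind(c(0.45, 0.40, 0.45, 0.35, 0.40),
             c(-0.10, 0.15, 0.10, 0.20, -0.15))
  tau_e <- c(0.30, 0.28, 0.25, 0.32, 0.30)
  tau_u <- c(0.18, 0.20, 0.15, 0.16, 0.22)
  list(R0 = reconstruct_covariance(r, tau_e),
       G0 = reconstruct_covariance(s, tau_u))
}

# simulate phenotypes directly from the multi-trait model:
# y = fixed effects + u (gene-dropped, G0 x A) + e (iid rows, R0)
mtm_sim <- function(n, seed, n_herds = max(5L, n %/% 40L)) {
  truth <- mtm_truth()
  t <- nrow(truth$R0)
  pop <- simulate_population(study_design(n_cows = n, n_herds = n_herds,
                                          n_generations = 3L),
                             seed = seed)
  u <- simulate_genetic_effects(pop$pedigree, truth$G0, seed = seed + 1L)
  set.seed(seed + 2L)
  b <- default_beta()
  cv <- pop$covariates
  herds <- sort(unique(cv$herd))
  herd_eff <- stats::rnorm(length(herds), 0, b$herd_sd)
  names(herd_eff) <- herds
  sea <- c(S1 = 0, S2 = 0.1, S3 = -0.1)
  fe <- b$dim * cv$dim + b$wilmink * exp(-0.05 * cv$dim) +
    b$afc * (cv$afc - 24) + b$afc2 * (cv$afc - 24)^2 +
    sea[cv$season] + ifelse(cv$sire_code == "K2", 0.15, 0) +
    herd_eff[cv$herd]
  e <- matrix(stats::rnorm(n * t), n, t) %*% chol(truth$R0)
  y <- matrix(fe, n, t) + u[cv$animal, ] + e
  colnames(y) <- paste0("T", seq_len(t))
  list(phenotypes = cbind(cv, as.data.frame(y)), pedigree = pop$pedigree,
       truth = truth)
}

# the multi-trait recovery fit, shared across tests
mtm_recovery_fit <- function() {
  fixture("mtm_recovery_fit", function() {
    sim <- fixture("mtm_recovery_sim", function() mtm_sim(1200L, 31L))
    fit_mtm(sim$phenotypes, sim$pedigree, k = 2L, chains = 2L,
            iters = 6000L, burn_in = 1500L, thin = 10L, seed = 13L)
  })
}

# truth rescaled to the standardized scale the sampler works on
standardized_truth <- function(sim) {
  y <- as.matrix(sim$phenotypes[, paste0("T", 1:5)])
  sds <- apply(y, 2L, stats::sd)
  d <- tcrossprod(sds)
  list(R0 = sim$truth$R0 / d, G0 = sim$truth$G0 / d)
}
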
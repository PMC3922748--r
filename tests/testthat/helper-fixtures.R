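# Shared fixtures. The expensive MCMC fits are built once per test run
# and cached here, so several test files can interrogate the same
# posterior without refitting.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, envir = fixture_env)
}

# a small pedigreed data set used by several cheap tests
small_sim <- function() {
  fixture("small_sim", function() {
    des <- study_design(n_cows = 300L, n_herds = 15L, n_generations = 2L)
    simulate_dataset(des, default_truth(), seed = 42L)
  })
}

# the main recovery data set: 2000 cows, 3-generation pedigree
recovery_sim <- function() {
  fixture("recovery_sim", function() {
    des <- study_design(n_cows = 2000L, n_herds = 50L, n_generations = 3L)
    simulate_dataset(des, default_truth(), seed = 7L)
  })
}

# multi-trait fit of the recovery data (shared by the covariance
# recovery, heritability-band and consistency checks)
recovery_mtm <- function() {
  fixture("recovery_mtm", function() {
    sim <- recovery_sim()
    fit_mtm(sim$phenotypes, sim$pedigree, k = 2L, chains = 2L,
            iters = 8000L, burn_in = 2000L, thin = 10L, seed = 3L)
  })
}

# SEM fit of the recovery data on the true chain structure
recovery_sem <- function() {
  fixture("recovery_sem", function() {
    sim <- recovery_sim()
    fit_sem(sim$phenotypes, sim$pedigree,
            chain_structure(sim$truth$traits), k = 2L, chains = 2L,
            iters = 10000L, burn_in = 2500L, thin = 10L, seed = 11L)
  })
}

# conjugate posterior draws of a covariance matrix given iid
# multivariate-normal rows: inverse-Wishart with a vague prior. Used to
# feed the IC machinery posterior covariance samples without an MCMC
# run.
covariance_posterior_draws <- function(y, n_draws = 400L) {
  n <- nrow(y); t <- ncol(y)
  scatter <- crossprod(sweep(y, 2L, colMeans(y)))
  df <- n - 1L + t + 1L
  prec <- stats::rWishart(n_draws, df, solve(scatter))
  arr <- array(NA_real_, c(t, t, n_draws))
  for (s in seq_len(n_draws)) arr[, , s] <- solve(prec[, , s])
  dimnames(arr) <- list(colnames(y), colnames(y), NULL)
  arr
}

# simulate iid reduced-form data from an acyclic lambda matrix with
# unit residual variances: y = (I - L)^-1 e
simulate_reduced_form <- function(lambda, n, psi = NULL) {
  t <- nrow(lambda)
  if (is.null(psi)) psi <- rep(1, t)
  e <- matrix(stats::rnorm(n * t), n, t) %*% diag(sqrt(psi), t)
  y <- e %*% t(solve(diag(t) - lambda))
  colnames(y) <- paste0("T", seq_len(t))
  y
}

# lambda matrix of a chain 1 -> 2 -> ... -> t with equal coefficients
chain_lambda <- function(t, coef = 0.9) {
  L <- matrix(0, t, t)
  for (i in seq_len(t - 1L)) L[i + 1L, i] <- coef
  L
}

# adjacency matrix (skeleton) of a pdag, for equality comparisons
pdag_adjacency <- function(g) {
  n <- length(g$nodes)
  A <- matrix(FALSE, n, n)
  for (r in seq_len(nrow(g$edges))) {
    A[g$edges$from[r], g$edges$to[r]] <- TRUE
    A[g$edges$to[r], g$edges$from[r]] <- TRUE
  }
  A
}

# d-separation skeleton of a DAG given as a lambda pattern: i adjacent j
# iff lambda[i,j] or lambda[j,i] nonzero
dag_skeleton <- function(lambda) {
  A <- (lambda != 0) | (t(lambda) != 0)
  diag(A) <- FALSE
  A
}

# directed edge set of a pdag as "from->to" strings (directed marks only)
pdag_directed_edges <- function(g) {
  d <- g$edges[g$edges$mark == "directed", , drop = FALSE]
  if (nrow(d) == 0L) return(character(0))
  paste0(d$from, "->", d$to)
}
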
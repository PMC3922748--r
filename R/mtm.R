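covariate_cols <- c("animal", "herd", "dim", "afc", "season", "sire_code")

#' Standardize phenotypes to mean 0, SD 1
#'
#' Scale differences between traits are removed before model fitting;
#' the per-trait centre and scale are returned so estimates can be
#' back-transformed.
#'
#' @param phenotypes data frame or matrix holding the trait columns.
#' @param traits trait column names; default: all numeric non-covariate
#'   columns.
#' @return list with \code{y} (matrix, standardized), \code{center},
#'   \code{scale} (named per-trait).
#' @export
standardize_phenotypes <- function(phenotypes, traits = NULL) {
  if (is.null(traits)) {
    if (is.matrix(phenotypes)) traits <- colnames(phenotypes)
    else traits <- setdiff(names(phenotypes)[vapply(phenotypes, is.numeric,
                                                    NA)],
                           covariate_cols)
  }
  y <- as.matrix(as.data.frame(phenotypes)[, traits, drop = FALSE])
  ctr <- colMeans(y)
  scl <- apply(y, 2L, stats::sd)
  if (any(scl <= 0 | !is.finite(scl))) {
    bad <- traits[scl <= 0 | !is.finite(scl)]
    stop("zero-variance trait(s): ", paste(bad, collapse = ", "))
  }
  y <- sweep(sweep(y, 2L, ctr), 2L, scl, "/")
  list(y = y, center = ctr, scale = scl)
}

#' Fixed-effect design matrix
#'
#' Columns: intercept; days in milk modelled by a Wilmink pair
#' \{DIM, exp(-wilmink_exponent * DIM)\}; age at first calving and its
#' square; reference-coded dummies for calving season, sire code and
#' herd. An error lists the offending columns if the coded matrix is
#' rank deficient.
#'
#' @param covariates data frame with columns \code{dim}, \code{afc},
#'   \code{season}, \code{sire_code}, \code{herd}.
#' @param wilmink_exponent exponent of the Wilmink lactation-curve term
#'   (per day; the canonical value is 0.05).
#' @return numeric design matrix (n x p), full column rank.
#' @export
build_design_matrices <- function(covariates, wilmink_exponent = 0.05) {
  need <- c("dim", "afc", "season", "sire_code", "herd")
  miss <- setdiff(need, names(covariates))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  df <- data.frame(
    dim = as.numeric(covariates$dim),
    wilmink = exp(-wilmink_exponent * as.numeric(covariates$dim)),
    afc = as.numeric(covariates$afc),
    afc2 = as.numeric(covariates$afc)^2,
    season = factor(covariates$season),
    sire_code = factor(covariates$sire_code),
    herd = factor(covariates$herd))
  ## drop single-level factors (reference coding leaves no column)
  for (f in c("season", "sire_code", "herd")) {
    if (nlevels(df[[f]]) < 2L) df[[f]] <- NULL
  }
  X <- stats::model.matrix(~ ., data = df)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop, collapse = ", "))
  }
  X
}

#' Choose the latent-factor dimension from a principal component analysis
#'
#' The number of factors is the smallest k whose leading eigenvalues of
#' the trait correlation matrix cumulatively explain at least
#' \code{threshold} of the variance.
#'
#' @param phenotypes trait data (data frame or matrix, >= 2 traits).
#' @param threshold fraction of variance to explain, in (0, 1\].
#' @param traits optional trait column names.
#' @return integer k.
#' @export
choose_num_factors <- function(phenotypes, threshold = 0.90,
                               traits = NULL) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  y <- standardize_phenotypes(phenotypes, traits)$y
  if (ncol(y) < 2L) stop("need at least 2 traits")
  ev <- eigen(stats::cor(y), symmetric = TRUE, only.values = TRUE)$values
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= threshold - 1e-12)[1L])
}

#' Reconstruct a covariance matrix from loadings and remaining variances
#'
#' The latent-variable model implies variance
#' \eqn{\sum_k l_{k,i}^2 + \tau_i^2} for trait i and covariance
#' \eqn{\sum_k l_{k,i} l_{k,j}} between traits i and j, i.e.
#' \eqn{\Sigma = L'L + diag(\tau^2)}.
#'
#' @param loadings k x t matrix of loadings.
#' @param remaining length-t vector of remaining variances (> 0).
#' @return t x t symmetric positive-definite covariance matrix.
#' @export
reconstruct_covariance <- function(loadings, remaining) {
  loadings <- as.matrix(loadings)
  if (any(remaining <= 0)) stop("remaining variances must be positive")
  if (ncol(loadings) != length(remaining))
    stop("loadings columns must match remaining variances")
  crossprod(loadings) + diag(remaining, length(remaining))
}

#' Fit the Bayesian latent-factor multi-trait animal model
#'
#' Gibbs sampler for \eqn{y = X\beta + Zu + e} with
#' \eqn{u \sim N(0, G_0 \otimes A)}, \eqn{e \sim N(0, R_0 \otimes I)},
#' where both covariance matrices carry a latent-factor structure:
#' k factor loadings per trait plus an independent remaining variance
#' bounded below by \code{variance_floor} (uniform \[floor, Inf) prior,
#' sampled by inverse-CDF truncation, never clamped). Phenotypes are
#' standardized internally. Posterior samples of the reconstructed
#' (G0, R0) are the substrate of the IC causal search.
#'
#' @param phenotypes data frame: covariate columns \code{animal, herd,
#'   dim, afc, season, sire_code} plus one column per trait.
#' @param pedigree a \code{pedigree} containing all phenotyped animals.
#' @param traits trait columns (default: every numeric non-covariate
#'   column).
#' @param k number of latent factors (1 <= k < t); default from
#'   [choose_num_factors()] at the 90\% threshold.
#' @param variance_floor lower bound for remaining variances (default
#'   0.02, i.e. at least 2\% of each standardized trait's variance stays
#'   trait-specific).
#' @param wilmink_exponent see [build_design_matrices()].
#' @param chains,iters,burn_in,thin MCMC run lengths (per chain).
#' @param seed integer seed; the full run is deterministic given the
#'   configuration and seed.
#' @param prune prune the pedigree to phenotyped animals and their
#'   ancestors before building the genetic precision matrix.
#' @return object of class \code{mtm_fit}.
#' @export
fit_mtm <- function(phenotypes, pedigree, traits = NULL, k = NULL,
                    variance_floor = 0.02, wilmink_exponent = 0.05,
                    chains = 4L, iters = 20000L, burn_in = 5000L,
                    thin = 10L, seed = 1L, prune = TRUE) {
  std <- standardize_phenotypes(phenotypes, traits)
  traits <- colnames(std$y)
  t <- length(traits)
  if (is.null(k)) k <- choose_num_factors(phenotypes, traits = traits)
  if (k < 1L || k >= t) stop("k must satisfy 1 <= k < number of traits")
  if (variance_floor <= 0) stop("variance_floor must be > 0")
  if (iters <= burn_in) stop("need at least one post-burn-in iteration")
  n <- nrow(std$y)
  if (n < 3L) stop("need at least 3 records")

  herd_n <- table(phenotypes$herd)
  if (any(herd_n < 2L))
    warning(sum(herd_n < 2L),
            " herd(s) have fewer than 2 phenotyped cows")

  X <- build_design_matrices(phenotypes, wilmink_exponent)
  ped <- if (prune) prune_pedigree(pedigree, phenotypes$animal) else pedigree
  zidx <- match(phenotypes$animal, ped$animal)
  if (anyNA(zidx)) stop("phenotyped animal(s) missing from the pedigree")
  Q <- ainverse_sparse(ped)
  XtX_chol <- chol(crossprod(X))

  set.seed(seed)
  runs <- lapply(seq_len(chains), function(ch)
    gibbs_mtm_cpp(std$y, X, XtX_chol, Q, zidx - 1L, as.integer(k),
                  variance_floor, variance_floor, as.integer(iters),
                  as.integer(burn_in), as.integer(thin), TRUE))

  S <- length(runs[[1L]]$deviance)
  G0 <- array(NA_real_, c(t, t, chains * S),
              dimnames = list(traits, traits, NULL))
  R0 <- G0
  dev <- matrix(NA_real_, S, chains)
  lpost <- matrix(NA_real_, S, chains)
  mu_mean <- 0; tau2e_mean <- 0; beta_mean <- 0
  for (ch in seq_len(chains)) {
    idx <- (ch - 1L) * S + seq_len(S)
    G0[, , idx] <- runs[[ch]]$G0
    R0[, , idx] <- runs[[ch]]$R0
    dev[, ch] <- runs[[ch]]$deviance
    lpost[, ch] <- runs[[ch]]$logpost
    mu_mean <- mu_mean + runs[[ch]]$mu_mean / chains
    tau2e_mean <- tau2e_mean + runs[[ch]]$tau2e_mean / chains
    beta_mean <- beta_mean + runs[[ch]]$beta_mean / chains
  }
  R0_mean <- apply(R0, c(1L, 2L), mean)
  dev_at_mean <- mvn_deviance(std$y, mu_mean, R0_mean)
  dic <- compute_dic(as.vector(dev), dev_at_mean)

  samples <- posterior_covariances(
    R0, G0, chain = rep(seq_len(chains), each = S),
    iter = rep(burn_in + thin * seq_len(S), chains))
  diag_tab <- covariance_diagnostics(R0, G0, chains, S)

  structure(list(samples = samples,
                 G0_mean = apply(G0, c(1L, 2L), mean),
                 R0_mean = R0_mean,
                 beta_mean = structure(beta_mean,
                                       dimnames = list(colnames(X), traits)),
                 mu_mean = mu_mean, y = std$y,
                 deviance = dev, logpost = lpost, dic = dic,
                 diagnostics = diag_tab,
                 scaling = list(center = std$center, scale = std$scale),
                 traits = traits, k = k,
                 config = list(variance_floor = variance_floor,
                               wilmink_exponent = wilmink_exponent,
                               chains = chains, iters = iters,
                               burn_in = burn_in, thin = thin,
                               seed = seed)),
            class = "mtm_fit")
}

conditional_deviance <- function(y, mu, sigma2) {
  n <- nrow(y)
  sum(vapply(seq_len(ncol(y)), function(i)
    n * log(2 * pi * sigma2[i]) + sum((y[, i] - mu[, i])^2) / sigma2[i],
    0))
}

## -2 log N(y_j | mu_j, Sigma) summed over rows
mvn_deviance <- function(y, mu, sigma) {
  n <- nrow(y); t <- ncol(y)
  L <- chol(sigma)
  w <- forwardsolve(t(L), t(y - mu))
  n * (t * log(2 * pi) + 2 * sum(log(diag(L)))) + sum(w^2)
}

## ESS and split-Rhat per covariance entry (loadings themselves are not
## identified, so diagnostics are computed on the reconstructed
## covariances only)
covariance_diagnostics <- function(R0, G0, chains, S) {
  t <- dim(R0)[1L]
  out <- list()
  for (mat in c("R0", "G0")) {
    arr <- if (mat == "R0") R0 else G0
    for (i in seq_len(t)) for (j in i:t) {
      x <- matrix(arr[i, j, ], S, chains)
      out[[length(out) + 1L]] <- data.frame(
        matrix = mat, i = i, j = j,
        ess = effective_sample_size(x),
        rhat = split_rhat(x))
    }
  }
  do.call(rbind, out)
}

#' Effective sample size of an MCMC trace
#'
#' \eqn{ESS = N / (1 + 2\sum_t \hat\rho_t)} with the sum truncated by the
#' initial-positive-sequence rule on pairs of autocorrelations. For a
#' matrix (iterations x chains), per-chain ESS values are summed.
#'
#' @param x numeric vector, or matrix with one column per chain.
#' @return effective sample size (0, with a warning, for a constant
#'   chain).
#' @export
effective_sample_size <- function(x) {
  if (is.matrix(x)) return(sum(apply(x, 2L, effective_sample_size)))
  n <- length(x)
  if (n < 10L) stop("need at least 10 samples")
  if (stats::sd(x) == 0) {
    warning("constant chain: effective sample size is 0")
    return(0)
  }
  rho <- stats::acf(x, lag.max = min(n - 2L, 10000L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  tau <- 0
  i <- 1L
  while (i < length(rho)) {
    g <- rho[i] + rho[i + 1L]
    if (g <= 0) break
    tau <- tau + g
    i <- i + 2L
  }
  min(n, n / (1 + 2 * tau))
}

#' Split-Rhat convergence diagnostic
#'
#' Each chain is split in half and the usual potential-scale-reduction
#' factor computed across the resulting half-chains.
#'
#' @param x matrix, iterations x chains (a vector is treated as one
#'   chain).
#' @return Rhat (NA for constant chains).
#' @export
split_rhat <- function(x) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1L):n, , drop = FALSE])
  mns <- colMeans(sub)
  vrs <- apply(sub, 2L, stats::var)
  W <- mean(vrs)
  B <- half * stats::var(mns)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Implied heritabilities from an mtm_fit
#'
#' Per posterior sample and trait, \eqn{h^2 = \sigma^2_g /
#' (\sigma^2_g + \sigma^2_e)} from the reconstructed covariance
#' diagonals on the standardized scale.
#'
#' @param fit an \code{mtm_fit}.
#' @return matrix samples x traits of heritabilities.
#' @export
implied_heritability <- function(fit) {
  stopifnot(inherits(fit, "mtm_fit"))
  t <- length(fit$traits)
  g <- t(apply(fit$samples$G0, 3L, diag))
  e <- t(apply(fit$samples$R0, 3L, diag))
  if (t == 1L) { g <- t(g); e <- t(e) }
  h2 <- g / (g + e)
  colnames(h2) <- fit$traits
  h2
}

#' @export
print.mtm_fit <- function(x, ...) {
  cfg <- x$config
  cat("Bayesian multi-trait animal model (latent-factor covariances)\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  k =", x$k, "factors per covariance structure, floor",
      cfg$variance_floor, "\n")
  cat("  MCMC:", cfg$chains, "chain(s) x", cfg$iters, "iterations,",
      "burn-in", cfg$burn_in, ", thin", cfg$thin, "->",
      dim(x$samples$R0)[3L], "samples\n")
  cat(sprintf("  DIC %.1f (pD %.1f)\n", x$dic$dic, x$dic$pd))
  cat(sprintf("  diagnostics: min ESS %.0f, max split-Rhat %.3f\n",
              min(x$diagnostics$ess), max(x$diagnostics$rhat,
                                          na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.mtm_fit <- function(object, ...) {
  t <- length(object$traits)
  g <- object$samples$G0; r <- object$samples$R0
  h2 <- implied_heritability(object)
  rows <- list()
  for (i in seq_len(t)) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("sigma2_g ", object$traits[i]),
      mean = mean(g[i, i, ]), sd = stats::sd(g[i, i, ]))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("sigma2_e ", object$traits[i]),
      mean = mean(r[i, i, ]), sd = stats::sd(r[i, i, ]))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("h2 ", object$traits[i]),
      mean = mean(h2[, i]), sd = stats::sd(h2[, i]))
  }
  for (i in seq_len(t - 1L)) for (j in (i + 1L):t) {
    rg <- g[i, j, ] / sqrt(g[i, i, ] * g[j, j, ])
    re <- r[i, j, ] / sqrt(r[i, i, ] * r[j, j, ])
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("r_g ", object$traits[i], ",", object$traits[j]),
      mean = mean(rg), sd = stats::sd(rg))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("r_e ", object$traits[i], ",", object$traits[j]),
      mean = mean(re), sd = stats::sd(re))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
coef.mtm_fit <- function(object, ...) object$beta_mean

#' @export
residuals.mtm_fit <- function(object, ...) object$y - object$mu_mean
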
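#' Structural-coefficient pattern of a recursive SEM
#'
#' Defines which entries of the t x t matrix Lambda are free structural
#' coefficients (parent trait -> child trait) and which are fixed at
#' zero. The diagonal is zero and the free pattern must be acyclic.
#'
#' @param traits trait names.
#' @param edges data frame with character columns \code{parent},
#'   \code{child} (one row per free coefficient), or NULL for the empty
#'   structure.
#' @return object of class \code{lambda_structure}.
#' @export
lambda_structure <- function(traits, edges = NULL) {
  t <- length(traits)
  free <- matrix(FALSE, t, t, dimnames = list(traits, traits))
  if (!is.null(edges) && nrow(edges)) {
    unk <- setdiff(c(edges$parent, edges$child), traits)
    if (length(unk)) stop("structure references unknown trait(s): ",
                          paste(unique(unk), collapse = ", "))
    if (any(edges$parent == edges$child))
      stop("lambda must have a zero diagonal")
    free[cbind(match(edges$child, traits), match(edges$parent, traits))] <-
      TRUE
  }
  if (lambda_cyclic(free)) stop("cyclic structure: the free pattern of ",
                                "lambda must be acyclic")
  structure(list(traits = traits, free = free), class = "lambda_structure")
}

#' A fully ordered causal chain structure
#'
#' @param traits traits in causal order (first causes second, etc.).
#' @return a \code{lambda_structure} with edges trait\[i\] -> trait\[i+1\].
#' @export
chain_structure <- function(traits) {
  if (length(traits) < 2L) return(lambda_structure(traits))
  lambda_structure(traits, data.frame(
    parent = traits[-length(traits)], child = traits[-1L],
    stringsAsFactors = FALSE))
}

#' Read / write a structure as a parent,child TSV edge list
#' @param path file path.
#' @param traits trait universe (edges may omit isolated traits).
#' @return a \code{lambda_structure}.
#' @export
read_lambda_structure <- function(path, traits) {
  ed <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character")
  lambda_structure(traits, ed)
}

#' @rdname read_lambda_structure
#' @param structure a \code{lambda_structure} to write.
#' @export
write_lambda_structure <- function(structure, path) {
  idx <- which(structure$free, arr.ind = TRUE)
  ed <- data.frame(parent = structure$traits[idx[, 2L]],
                   child = structure$traits[idx[, 1L]])
  utils::write.table(ed, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.lambda_structure <- function(x, ...) {
  idx <- which(x$free, arr.ind = TRUE)
  cat("SEM structure over", length(x$traits), "traits:",
      nrow(idx), "free coefficient(s)\n")
  for (r in seq_len(nrow(idx)))
    cat("  ", x$traits[idx[r, 2L]], "->", x$traits[idx[r, 1L]], "\n")
  invisible(x)
}

#' Fit a recursive structural equation model
#'
#' Gibbs sampler for \eqn{y = (\Lambda \otimes I) y + X\beta^* + Zu^* +
#' e^*}: causal parents enter the child trait's equation as covariates
#' (flat prior, conditionally normal), the residual covariance is
#' diagonal (\eqn{\Psi_0}, which identifies the structural
#' coefficients), and the direct genetic covariance \eqn{G_0^*} carries
#' the same latent-factor structure and variance floor as the
#' multi-trait model.
#'
#' @param phenotypes,pedigree,traits,wilmink_exponent,chains,iters,burn_in,thin,seed,prune
#'   as in [fit_mtm()].
#' @param structure a [lambda_structure()] (or data frame of
#'   parent,child edges over the traits).
#' @param k latent-factor dimension of the direct-genetic covariance
#'   (default 2).
#' @param variance_floor floor of the remaining genetic variances.
#' @param psi_floor lower bound for the SEM residual variances
#'   (default 0: the diagonal residual covariance needs no floor for
#'   identifiability, and near-zero direct residual variances are a
#'   genuine feature of strongly coupled traits).
#' @return object of class \code{sem_fit}.
#' @export
fit_sem <- function(phenotypes, pedigree, structure, traits = NULL,
                    k = 2L, variance_floor = 0.02, psi_floor = 0,
                    wilmink_exponent = 0.05, chains = 4L, iters = 20000L,
                    burn_in = 5000L, thin = 10L, seed = 1L, prune = TRUE) {
  if (is.data.frame(structure)) {
    if (is.null(traits)) stop("traits must be given with a raw edge list")
    structure <- lambda_structure(traits, structure)
  }
  stopifnot(inherits(structure, "lambda_structure"))
  traits <- structure$traits
  std <- standardize_phenotypes(phenotypes, traits)
  t <- length(traits)
  if (k < 1L || k > t) stop("k must satisfy 1 <= k <= number of traits")
  if (iters <= burn_in) stop("need at least one post-burn-in iteration")

  X <- build_design_matrices(phenotypes, wilmink_exponent)
  ped <- if (prune) prune_pedigree(pedigree, phenotypes$animal) else pedigree
  zidx <- match(phenotypes$animal, ped$animal)
  if (anyNA(zidx)) stop("phenotyped animal(s) missing from the pedigree")
  Q <- ainverse_sparse(ped)
  XtX_chol <- chol(crossprod(X))
  lam_free <- matrix(as.integer(structure$free), t, t)

  set.seed(seed)
  runs <- lapply(seq_len(chains), function(ch)
    gibbs_sem_cpp(std$y, X, XtX_chol, Q, zidx - 1L, lam_free,
                  as.integer(k), variance_floor, psi_floor,
                  as.integer(iters), as.integer(burn_in),
                  as.integer(thin)))

  S <- length(runs[[1L]]$deviance)
  ## C++ emits coefficients child-major: for i in rows, for parents of i
  lam_names <- character(0)
  for (i in seq_len(t)) for (p in seq_len(t)) if (structure$free[i, p])
    lam_names <- c(lam_names, paste0(traits[i], "<-", traits[p]))
  nl <- length(lam_names)
  G0 <- array(NA_real_, c(t, t, chains * S),
              dimnames = list(traits, traits, NULL))
  psi <- matrix(NA_real_, chains * S, t, dimnames = list(NULL, traits))
  lambda <- matrix(NA_real_, chains * S, nl,
                   dimnames = list(NULL, lam_names))
  dev <- matrix(NA_real_, S, chains)
  lpost <- matrix(NA_real_, S, chains)
  mu_mean <- 0; psi_mean <- 0
  for (ch in seq_len(chains)) {
    idx <- (ch - 1L) * S + seq_len(S)
    G0[, , idx] <- runs[[ch]]$G0
    psi[idx, ] <- t(runs[[ch]]$psi)
    if (nl) lambda[idx, ] <- t(runs[[ch]]$lambda)
    dev[, ch] <- runs[[ch]]$deviance
    lpost[, ch] <- runs[[ch]]$logpost
    mu_mean <- mu_mean + runs[[ch]]$mu_mean / chains
    psi_mean <- psi_mean + runs[[ch]]$psi_mean / chains
  }
  dev_at_mean <- conditional_deviance(std$y, mu_mean, psi_mean)
  dic <- compute_dic(as.vector(dev), dev_at_mean)

  lambda_mean_mat <- matrix(0, t, t, dimnames = list(traits, traits))
  if (nl) {
    pos <- 0L
    for (i in seq_len(t)) for (p in seq_len(t)) if (structure$free[i, p]) {
      pos <- pos + 1L
      lambda_mean_mat[i, p] <- mean(lambda[, pos])
    }
  }

  base::structure(list(structure = structure, traits = traits,
                 lambda = lambda, lambda_mean = lambda_mean_mat,
                 G0_star = G0, psi = psi,
                 G0_star_mean = apply(G0, c(1L, 2L), mean),
                 psi_mean_draws = colMeans(psi),
                 mu_mean = mu_mean, y = std$y,
                 deviance = dev, logpost = lpost, dic = dic,
                 scaling = list(center = std$center, scale = std$scale),
                 k = k,
                 config = list(variance_floor = variance_floor,
                               psi_floor = psi_floor,
                               wilmink_exponent = wilmink_exponent,
                               chains = chains, iters = iters,
                               burn_in = burn_in, thin = thin,
                               seed = seed)),
            class = "sem_fit")
}

#' @export
print.sem_fit <- function(x, ...) {
  cfg <- x$config
  cat("Recursive structural equation model (diagonal residuals)\n")
  cat("  traits:", paste(x$traits, collapse = ", "), "\n")
  cat("  free coefficients:", ncol(x$lambda), " genetic factors:", x$k,
      "\n")
  cat("  MCMC:", cfg$chains, "chain(s) x", cfg$iters, "iterations ->",
      nrow(x$psi), "samples\n")
  if (ncol(x$lambda)) {
    cat("  structural coefficients (posterior mean +- SD):\n")
    for (j in seq_len(ncol(x$lambda)))
      cat(sprintf("    %s = %.3f +- %.3f\n", colnames(x$lambda)[j],
                  mean(x$lambda[, j]), stats::sd(x$lambda[, j])))
  }
  cat(sprintf("  DIC %.1f (pD %.1f)\n", x$dic$dic, x$dic$pd))
  invisible(x)
}

#' @export
coef.sem_fit <- function(object, ...) colMeans(object$lambda)

#' Structural coefficients on the standardized or original trait scale
#'
#' The sampler works on standardized traits; a coefficient on the
#' original measurement scale (e.g. g/kg milk) is obtained by rescaling
#' with the ratio of the child and parent sample SDs:
#' \eqn{\lambda^{orig} = \lambda^{std} \cdot sd(child)/sd(parent)}.
#'
#' @param fit a \code{sem_fit}.
#' @param scale \code{"standardized"} (as sampled) or \code{"original"}.
#' @return matrix of posterior draws (samples x coefficients).
#' @export
structural_coefficients <- function(fit,
                                    scale = c("original", "standardized")) {
  stopifnot(inherits(fit, "sem_fit"))
  scale <- match.arg(scale)
  lam <- fit$lambda
  if (scale == "original" && ncol(lam)) {
    sds <- fit$scaling$scale
    for (j in seq_len(ncol(lam))) {
      pc <- strsplit(colnames(lam)[j], "<-", fixed = TRUE)[[1L]]
      lam[, j] <- lam[, j] * sds[pc[1L]] / sds[pc[2L]]
    }
  }
  lam
}

#' @export
residuals.sem_fit <- function(object, ...) object$y - object$mu_mean

#' @export
summary.sem_fit <- function(object, ...) {
  t <- length(object$traits)
  g <- object$G0_star
  rows <- list()
  for (i in seq_len(t)) {
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("sigma2_g ", object$traits[i]),
      mean = mean(g[i, i, ]), sd = stats::sd(g[i, i, ]))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("sigma2_e ", object$traits[i]),
      mean = mean(object$psi[, i]), sd = stats::sd(object$psi[, i]))
  }
  for (j in seq_len(ncol(object$lambda)))
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = paste0("lambda ", colnames(object$lambda)[j]),
      mean = mean(object$lambda[, j]), sd = stats::sd(object$lambda[, j]))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reduced-form covariances implied by SEM parameters
#'
#' Rearranging \eqn{y = \Lambda y + X\beta^* + Zu^* + e^*} gives
#' \eqn{y = (I-\Lambda)^{-1}(X\beta^* + Zu^* + e^*)}, so the genetic and
#' residual covariances on the multi-trait scale are
#' \eqn{(I-\Lambda)^{-1} G_0^* (I-\Lambda)^{-T}} and
#' \eqn{(I-\Lambda)^{-1} \Psi_0 (I-\Lambda)^{-T}}.
#'
#' @param lambda t x t structural-coefficient matrix.
#' @param G0_star direct-genetic covariance.
#' @param Psi0 direct residual variances (vector or diagonal matrix).
#' @return list with \code{G0} and \code{R0} (implied covariances).
#' @export
reduced_form_covariances <- function(lambda, G0_star, Psi0) {
  t <- nrow(as.matrix(lambda))
  im <- diag(t) - as.matrix(lambda)
  sol <- tryCatch(solve(im), error = function(e)
    stop("singular (I - lambda); the pattern must be acyclic"))
  if (!is.matrix(Psi0)) Psi0 <- diag(as.numeric(Psi0), t)
  list(G0 = sol %*% as.matrix(G0_star) %*% t(sol),
       R0 = sol %*% Psi0 %*% t(sol))
}

#' Deviance information criterion from a deviance trace
#'
#' \eqn{pD = \bar{D} - D(\bar\theta)} and \eqn{DIC = \bar{D} + pD},
#' where the deviance is -2 times the log-likelihood of the data
#' conditional on the sampled location effects (fixed effects, genetic
#' effects including their latent vectors, and structural coefficients)
#' under the model's residual covariance: the reconstructed \eqn{R_0}
#' for the multi-trait model, the diagonal \eqn{\Psi_0} for the SEM.
#' This shared focus makes the two models' DICs directly comparable.
#'
#' @param deviance vector of post-burn-in deviance evaluations (>= 30).
#' @param deviance_at_mean deviance at the posterior mean of the
#'   location parameters and residual variances.
#' @return list with \code{dic}, \code{pd}, \code{mean_deviance},
#'   \code{deviance_at_mean}.
#' @export
compute_dic <- function(deviance, deviance_at_mean) {
  deviance <- as.numeric(deviance)
  bad <- sum(!is.finite(deviance))
  if (bad > 0) stop("non-finite deviance draws: ", bad)
  if (length(deviance) < 30L)
    stop("need at least 30 deviance evaluations, got ", length(deviance))
  if (!is.finite(deviance_at_mean)) stop("non-finite deviance at mean")
  db <- mean(deviance)
  pd <- db - deviance_at_mean
  list(dic = db + pd, pd = pd, mean_deviance = db,
       deviance_at_mean = deviance_at_mean)
}

#' Compare a multi-trait fit and a SEM fit by DIC and variance components
#'
#' @param mtm an \code{mtm_fit}.
#' @param sem a \code{sem_fit} on the same traits and data.
#' @return object of class \code{model_comparison}: \code{report} (data
#'   frame: per-trait residual and genetic variances and pairwise
#'   correlations, posterior mean and SD under both models; SEM residual
#'   correlations are structurally zero and reported as NA) plus the two
#'   DIC/pD pairs and \code{delta_dic = DIC_SEM - DIC_MTM}.
#' @export
compare_models <- function(mtm, sem) {
  stopifnot(inherits(mtm, "mtm_fit"), inherits(sem, "sem_fit"))
  if (!identical(mtm$traits, sem$traits))
    stop("models were fitted to different trait sets")
  t <- length(mtm$traits)
  g1 <- mtm$samples$G0; r1 <- mtm$samples$R0
  g2 <- sem$G0_star
  rows <- list()
  add <- function(param, m1, s1, m2, s2)
    rows[[length(rows) + 1L]] <<- data.frame(
      parameter = param, mtm_mean = m1, mtm_sd = s1,
      sem_mean = m2, sem_sd = s2, stringsAsFactors = FALSE)
  for (i in seq_len(t)) {
    add(paste0("sigma2_e ", mtm$traits[i]),
        mean(r1[i, i, ]), stats::sd(r1[i, i, ]),
        mean(sem$psi[, i]), stats::sd(sem$psi[, i]))
  }
  for (i in seq_len(t - 1L)) for (j in (i + 1L):t) {
    re <- r1[i, j, ] / sqrt(r1[i, i, ] * r1[j, j, ])
    add(paste0("r_e ", mtm$traits[i], ",", mtm$traits[j]),
        mean(re), stats::sd(re), NA_real_, NA_real_)
  }
  for (i in seq_len(t)) {
    add(paste0("sigma2_g ", mtm$traits[i]),
        mean(g1[i, i, ]), stats::sd(g1[i, i, ]),
        mean(g2[i, i, ]), stats::sd(g2[i, i, ]))
  }
  for (i in seq_len(t - 1L)) for (j in (i + 1L):t) {
    rg1 <- g1[i, j, ] / sqrt(g1[i, i, ] * g1[j, j, ])
    rg2 <- g2[i, j, ] / sqrt(g2[i, i, ] * g2[j, j, ])
    add(paste0("r_g ", mtm$traits[i], ",", mtm$traits[j]),
        mean(rg1), stats::sd(rg1), mean(rg2), stats::sd(rg2))
  }
  report <- do.call(rbind, rows)
  structure(list(report = report,
                 dic_mtm = mtm$dic$dic, pd_mtm = mtm$dic$pd,
                 dic_sem = sem$dic$dic, pd_sem = sem$dic$pd,
                 delta_dic = sem$dic$dic - mtm$dic$dic),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (multi-trait vs SEM)\n")
  cat(sprintf("  DIC: multi-trait %.1f (pD %.1f), SEM %.1f (pD %.1f)\n",
              x$dic_mtm, x$pd_mtm, x$dic_sem, x$pd_sem))
  cat(sprintf("  delta DIC (SEM - MTM): %.1f%s\n", x$delta_dic,
              if (x$delta_dic < 0) "  [SEM better supported]" else ""))
  print(utils::head(x$report, 10L), digits = 3)
  if (nrow(x$report) > 10L) cat("  ...", nrow(x$report), "rows\n")
  invisible(x)
}
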
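#' Reference means and phenotypic standard deviations of milk fatty acids
#'
#' Per-trait location and scale (g/kg milk) used by the simulator to map
#' standardized phenotypes onto a realistic measurement scale: the 14
#' highest-concentration bovine milk fatty acids, ordered as in the
#' motivating study design.
#'
#' @return data frame with columns \code{trait}, \code{mean}, \code{sd}.
#' @export
milk_fa_reference <- function() {
  data.frame(
    trait = c("C4:0", "C6:0", "C8:0", "C10:0", "C12:0", "C14:0", "C16:0",
              "C18:0", "C10:1", "C12:1", "C14:1", "C16:1", "C18:1", "CLA"),
    mean = c(1.53, 0.97, 0.60, 1.32, 1.79, 5.05, 14.27, 3.80,
             0.16, 0.05, 0.59, 0.63, 7.87, 0.17),
    sd   = c(0.26, 0.17, 0.11, 0.28, 0.37, 0.77, 2.84, 0.84,
             0.04, 0.01, 0.13, 0.19, 1.20, 0.04),
    stringsAsFactors = FALSE)
}

#' Study design for the synthetic population
#'
#' Defaults emulate the motivating field study: 1902 first-lactation cows
#' on 397 herds with at least 3 cows per herd, days in milk between 63
#' and 282, a 4-generation pedigree, 3 calving seasons and 2 sire codes.
#'
#' @param n_cows number of phenotyped cows.
#' @param n_herds number of herds.
#' @param min_cows_per_herd minimum herd size.
#' @param dim_range integer range of days in milk.
#' @param n_generations pedigree generations including the phenotyped one
#'   (1 = phenotyped animals are founders).
#' @param n_seasons,n_sire_codes numbers of categories.
#' @param afc_mean,afc_sd age at first calving distribution (months).
#' @return object of class \code{study_design}.
#' @export
study_design <- function(n_cows = 1902L, n_herds = 397L,
                         min_cows_per_herd = 3L, dim_range = c(63L, 282L),
                         n_generations = 4L, n_seasons = 3L,
                         n_sire_codes = 2L, afc_mean = 24, afc_sd = 2) {
  d <- list(n_cows = as.integer(n_cows), n_herds = as.integer(n_herds),
            min_cows_per_herd = as.integer(min_cows_per_herd),
            dim_range = as.integer(dim_range),
            n_generations = as.integer(n_generations),
            n_seasons = as.integer(n_seasons),
            n_sire_codes = as.integer(n_sire_codes),
            afc_mean = afc_mean, afc_sd = afc_sd)
  if (d$n_cows < d$n_herds * d$min_cows_per_herd)
    stop("infeasible design: n_cows < n_herds * min_cows_per_herd")
  if (d$dim_range[1L] < 1L || d$dim_range[2L] > 500L ||
      d$dim_range[1L] > d$dim_range[2L])
    stop("infeasible design: dim_range must be increasing within [1, 500]")
  if (d$n_generations < 1L) stop("n_generations must be >= 1")
  class(d) <- "study_design"
  d
}

#' Generating truth of the recursive (SEM) simulation model
#'
#' The phenotypes are generated from the reduced form
#' \eqn{y = (I-\Lambda)^{-1}(X\beta + u + e)} on the standardized scale,
#' with gene-dropped additive effects \eqn{u} (covariance
#' \eqn{G_0^* \otimes A}) and independent residuals \eqn{e} (diagonal
#' \eqn{\Psi_0}), then mapped to g/kg using per-trait means/SDs.
#'
#' @param traits trait names (columns of the phenotype table).
#' @param lambda t x t structural-coefficient matrix; nonzero pattern must
#'   be acyclic, zero diagonal.
#' @param G0_star t x t direct-genetic covariance (PSD).
#' @param Psi0 length-t vector of direct residual variances (>= 0).
#' @param beta list of fixed-effect coefficients shared across traits:
#'   \code{dim}, \code{wilmink}, \code{afc}, \code{afc2},
#'   \code{season} (length n_seasons), \code{sire_code} (length
#'   n_sire_codes), \code{herd_sd} (SD of herd effects, drawn per herd).
#' @param trait_means,trait_sds per-trait location/scale on the g/kg
#'   scale; defaults looked up from [milk_fa_reference()] by trait name.
#' @return object of class \code{simulation_truth}.
#' @export
simulation_truth <- function(traits, lambda, G0_star, Psi0,
                             beta = default_beta(),
                             trait_means = NULL, trait_sds = NULL) {
  t <- length(traits)
  lambda <- as.matrix(lambda)
  stopifnot(all(dim(lambda) == t), nrow(as.matrix(G0_star)) == t,
            length(Psi0) == t)
  if (any(diag(lambda) != 0)) stop("lambda must have a zero diagonal")
  if (lambda_cyclic(lambda != 0)) stop("lambda pattern must be acyclic")
  ev <- eigen(G0_star, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("G0_star must be positive semi-definite")
  if (any(Psi0 < 0)) stop("Psi0 variances must be non-negative")
  ref <- milk_fa_reference()
  if (is.null(trait_means)) {
    trait_means <- ref$mean[match(traits, ref$trait)]
    trait_means[is.na(trait_means)] <- 0
  }
  if (is.null(trait_sds)) {
    trait_sds <- ref$sd[match(traits, ref$trait)]
    trait_sds[is.na(trait_sds)] <- 1
  }
  structure(list(traits = traits, lambda = lambda,
                 G0_star = as.matrix(G0_star), Psi0 = as.numeric(Psi0),
                 beta = beta, trait_means = as.numeric(trait_means),
                 trait_sds = as.numeric(trait_sds)),
            class = "simulation_truth")
}

lambda_cyclic <- function(pattern) {
  n <- nrow(pattern)
  dir <- which(pattern, arr.ind = TRUE)
  if (nrow(dir) == 0L) return(FALSE)
  ## lambda[i, p] != 0 means p -> i
  has_directed_cycle(n, data.frame(from = dir[, 2L], to = dir[, 1L]))
}

#' Default fixed-effect coefficients of the simulator
#'
#' Shared across traits: Wilmink pair, age at first calving (linear and
#' quadratic, centred at 24 months), season and sire-code contrasts,
#' and the SD of herd effects (drawn per herd at simulation time).
#'
#' @return named list of coefficients on the standardized trait scale.
#' @export
default_beta <- function() {
  list(dim = -0.002, wilmink = 0.5, afc = 0.03, afc2 = -0.005,
       season = c(0, 0.10, -0.10), sire_code = c(0, 0.15), herd_sd = 0.30)
}

#' Default generating truth: the de novo synthesis chain
#'
#' A 5-trait recursive chain C4:0 -> C6:0 -> C8:0 -> C10:0 -> C12:0 with
#' structural coefficients (1.05, 0.90, 0.85, 0.95), direct-genetic
#' variances (0.460, 0.114, 0.073, 0.066, 0.026) with exchangeable
#' direct-genetic correlation 0.3, and direct residual variances
#' (0.455, 0.010, 0.010, 0.010, 0.059), all on the standardized scale.
#'
#' @param rho_g exchangeable correlation among direct genetic effects.
#' @return a \code{simulation_truth}.
#' @export
default_truth <- function(rho_g = 0.3) {
  traits <- c("C4:0", "C6:0", "C8:0", "C10:0", "C12:0")
  lam <- matrix(0, 5, 5, dimnames = list(traits, traits))
  co <- c(1.05, 0.90, 0.85, 0.95)
  for (i in 1:4) lam[i + 1L, i] <- co[i]
  sg <- c(0.460, 0.114, 0.073, 0.066, 0.026)
  Rg <- matrix(rho_g, 5, 5); diag(Rg) <- 1
  G0s <- Rg * tcrossprod(sqrt(sg))
  psi <- c(0.455, 0.010, 0.010, 0.010, 0.059)
  simulation_truth(traits, lam, G0s, psi)
}

#' Simulate a pedigreed population and its covariates
#'
#' Builds a pedigree with \code{n_generations - 1} ancestral layers above
#' the phenotyped cows (each ancestral layer holds about half as many
#' animals as there are cows, of which 5\% are males), then assigns
#' herds (every herd gets at least the minimum, the remainder is spread
#' multinomially), days in milk (uniform on the design range), age at
#' first calving (normal), calving season and sire code (uniform
#' categorical).
#'
#' @param design a [study_design()].
#' @param seed integer seed; the output is reproducible given
#'   (design, seed).
#' @return list with \code{pedigree} and \code{covariates} (data frame
#'   with columns animal, herd, dim, afc, season, sire_code).
#' @export
simulate_population <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  n <- design$n_cows
  G <- design$n_generations
  rec <- list()
  prev_males <- prev_females <- character(0)
  if (G > 1L) {
    for (g in seq_len(G - 1L)) {
      size <- max(4L, round(0.49 * n))
      nm <- max(2L, round(0.05 * size))
      ids <- sprintf("G%d_%04d", g, seq_len(size))
      males <- ids[seq_len(nm)]
      females <- ids[-seq_len(nm)]
      if (g == 1L) {
        rec[[g]] <- data.frame(animal = ids, sire = "0", dam = "0",
                               stringsAsFactors = FALSE)
      } else {
        rec[[g]] <- data.frame(
          animal = ids,
          sire = sample(prev_males, size, replace = TRUE),
          dam = sample(prev_females, size, replace = TRUE),
          stringsAsFactors = FALSE)
      }
      prev_males <- males; prev_females <- females
    }
  }
  cows <- sprintf("C%04d", seq_len(n))
  if (G > 1L) {
    rec[[G]] <- data.frame(
      animal = cows,
      sire = sample(prev_males, n, replace = TRUE),
      dam = sample(prev_females, n, replace = TRUE),
      stringsAsFactors = FALSE)
  } else {
    rec[[1L]] <- data.frame(animal = cows, sire = "0", dam = "0",
                            stringsAsFactors = FALSE)
  }
  ped <- parse_pedigree(do.call(rbind, rec))

  ## herd sizes: guaranteed minimum, multinomial remainder
  base <- rep(design$min_cows_per_herd, design$n_herds)
  extra <- n - sum(base)
  if (extra > 0L) {
    add <- stats::rmultinom(1L, extra, rep(1, design$n_herds))[, 1L]
    base <- base + add
  }
  herd <- rep(sprintf("H%03d", seq_len(design$n_herds)), base)
  covariates <- data.frame(
    animal = cows,
    herd = sample(herd),   # shuffle cow-herd assignment
    dim = sample(seq(design$dim_range[1L], design$dim_range[2L]),
                 n, replace = TRUE),
    afc = round(stats::rnorm(n, design$afc_mean, design$afc_sd), 1),
    season = sprintf("S%d", sample.int(design$n_seasons, n, replace = TRUE)),
    sire_code = sprintf("K%d", sample.int(design$n_sire_codes, n,
                                          replace = TRUE)),
    stringsAsFactors = FALSE)
  list(pedigree = ped, covariates = covariates)
}

#' Gene-drop additive genetic effects down a pedigree
#'
#' Founders draw breeding values from N(0, G0_star); an offspring
#' receives the parent average plus a Mendelian-sampling deviation with
#' covariance \code{(0.5 - 0.25 (F_s + F_d)) * G0_star} (a missing parent
#' contributes 0 to the average and 0.25 to the Mendelian variance
#' factor), so that \code{Var(vec(u)) = G0_star \%x\% A}.
#'
#' @param ped a \code{pedigree}.
#' @param G0_star trait covariance of founder breeding values (PSD).
#' @param seed integer seed.
#' @return matrix animals x traits of breeding values, rownames =
#'   animal ids.
#' @export
simulate_genetic_effects <- function(ped, G0_star, seed = 1L) {
  G0_star <- as.matrix(G0_star)
  ev <- eigen(G0_star, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values), 1))
    stop("G0_star must be positive semi-definite")
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(G0_star)) # G = rt rt'
  set.seed(seed)
  m <- nrow(ped)
  t <- nrow(G0_star)
  u <- matrix(0, m, t, dimnames = list(ped$animal, colnames(G0_star)))
  if (m == 0L || all(G0_star == 0)) return(u)
  f <- inbreeding(ped)
  par <- parent_indices(ped)
  z <- matrix(stats::rnorm(m * t), m, t)
  for (i in seq_len(m)) {
    s <- par[i, 1L]; d <- par[i, 2L]
    pa <- (if (s > 0L) 0.5 * u[s, ] else 0) +
          (if (d > 0L) 0.5 * u[d, ] else 0)
    msv <- 1 -
      (if (s > 0L) 0.25 * (1 + f[s]) else 0) -
      (if (d > 0L) 0.25 * (1 + f[d]) else 0)
    u[i, ] <- pa + sqrt(msv) * drop(rt %*% z[i, ])
  }
  u
}

#' Simulate multi-trait phenotypes from the recursive generating model
#'
#' Per phenotyped animal, the standardized phenotype vector is
#' \eqn{y = (I-\Lambda)^{-1}(X\beta + u + e)} with \eqn{e \sim N(0,
#' \Psi_0)} independent across animals, then written on the g/kg scale
#' as \code{mean + sd * y}.
#'
#' @param truth a [simulation_truth()].
#' @param ped pedigree containing (at least) the phenotyped animals.
#' @param covariates covariate table from [simulate_population()].
#' @param seed integer seed.
#' @return phenotype data frame: \code{animal, herd, dim, afc, season,
#'   sire_code} followed by one column per trait (g/kg scale).
#' @export
simulate_phenotypes_from_sem <- function(truth, ped, covariates, seed = 1L) {
  stopifnot(inherits(truth, "simulation_truth"))
  t <- length(truth$traits)
  if (lambda_cyclic(truth$lambda != 0)) stop("lambda pattern must be acyclic")
  n <- nrow(covariates)
  u_all <- simulate_genetic_effects(ped, truth$G0_star, seed = seed)
  u <- u_all[covariates$animal, , drop = FALSE]

  set.seed(seed + 1L)
  b <- truth$beta
  herds <- sort(unique(covariates$herd))
  herd_eff <- stats::rnorm(length(herds), 0, b$herd_sd)
  names(herd_eff) <- herds
  seasons <- sort(unique(covariates$season))
  sea <- b$season[seq_along(seasons)]; names(sea) <- seasons
  codes <- sort(unique(covariates$sire_code))
  sc <- b$sire_code[seq_along(codes)]; names(sc) <- codes
  fe <- b$dim * covariates$dim +
    b$wilmink * exp(-0.05 * covariates$dim) +
    b$afc * (covariates$afc - 24) +
    b$afc2 * (covariates$afc - 24)^2 +
    sea[covariates$season] + sc[covariates$sire_code] +
    herd_eff[covariates$herd]
  xb <- matrix(fe, n, t)               # shared systematic part per trait

  e <- matrix(stats::rnorm(n * t), n, t) %*% diag(sqrt(truth$Psi0), t)
  sol <- solve(diag(t) - truth$lambda)
  y_std <- (xb + u + e) %*% t(sol)
  y <- sweep(sweep(y_std, 2L, truth$trait_sds, "*"), 2L,
             truth$trait_means, "+")
  colnames(y) <- truth$traits
  out <- cbind(covariates, as.data.frame(y, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' One-call synthetic data set: pedigree, covariates, phenotypes, truth
#'
#' @param design a [study_design()].
#' @param truth a [simulation_truth()] (default: the de novo chain).
#' @param seed integer seed driving the whole generation.
#' @return list with \code{pedigree}, \code{phenotypes} (covariates +
#'   trait columns), and \code{truth}.
#' @export
simulate_dataset <- function(design = study_design(),
                             truth = default_truth(), seed = 1L) {
  pop <- simulate_population(design, seed = seed)
  phen <- simulate_phenotypes_from_sem(truth, pop$pedigree,
                                       pop$covariates, seed = seed + 1000L)
  list(pedigree = pop$pedigree, phenotypes = phen, truth = truth)
}

#' Write a simulated data set to disk
#'
#' Writes \code{pedigree.csv} (readable by [read_pedigree()]),
#' \code{phenotypes.csv} and \code{truth.yaml} (the generating
#' parameters, for recovery checks).
#'
#' @param sim output of [simulate_dataset()].
#' @param dir output directory (created if absent).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- as.data.frame(sim$pedigree)
  ped$sire[is.na(ped$sire)] <- "0"
  ped$dam[is.na(ped$dam)] <- "0"
  utils::write.csv(ped, file.path(dir, "pedigree.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sim$phenotypes, file.path(dir, "phenotypes.csv"),
                   row.names = FALSE, quote = FALSE)
  tr <- sim$truth
  yaml::write_yaml(list(traits = tr$traits,
                        lambda = apply(tr$lambda, 1L, as.list),
                        G0_star = apply(tr$G0_star, 1L, as.list),
                        Psi0 = as.list(tr$Psi0),
                        trait_means = as.list(tr$trait_means),
                        trait_sds = as.list(tr$trait_sds)),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
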
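#' Molar-mass ratio of two saturated fatty acids
#'
#' Even-chain saturated fatty acids have formula CnH2nO2; the ratio of
#' molar masses converts unit-based (g/kg) structural coefficients to a
#' molar interpretation. Standard atomic weights are used (C 12.011,
#' H 1.008, O 15.999) and the ratio is reported to 2 decimals.
#'
#' @param fa_a,fa_b fatty-acid labels like \code{"C6:0"} (saturated
#'   only), or even chain lengths >= 4.
#' @return ratio M(fa_a) / M(fa_b), rounded to 2 decimals.
#' @export
molar_mass_ratio <- function(fa_a, fa_b) {
  round(molar_mass(fa_a) / molar_mass(fa_b), 2L)
}

molar_mass <- function(fa) {
  if (is.character(fa)) {
    m <- regmatches(fa, regexec("^C(\\d+):(\\d+)$", fa))[[1L]]
    if (length(m) != 3L) stop("cannot parse fatty-acid label '", fa, "'")
    if (as.integer(m[3L]) != 0L)
      stop("unsaturated species '", fa, "' not supported ",
           "(saturated-only utility)")
    fa <- as.integer(m[2L])
  }
  if (fa < 4L || fa %% 2L != 0L)
    stop("chain length must be an even integer >= 4")
  fa * 12.011 + 2L * fa * 1.008 + 2L * 15.999
}

#' Export a PDAG to DOT or TSV
#'
#' The TSV edge list (\code{from, to, mark, hpd_content}) round-trips
#' losslessly through [read_pdag_tsv()]; DOT renders undirected edges
#' without arrowheads.
#'
#' @param g a \code{pdag}.
#' @param path output file.
#' @param format \code{"dot"} or \code{"tsv"}.
#' @return \code{path}, invisibly.
#' @export
export_graph <- function(g, path, format = c("tsv", "dot")) {
  stopifnot(inherits(g, "pdag"))
  format <- match.arg(format)
  if (format == "tsv") {
    ed <- data.frame(from = g$nodes[g$edges$from], to = g$nodes[g$edges$to],
                     mark = g$edges$mark,
                     hpd_content = rep(g$hpd_content, nrow(g$edges)))
    utils::write.table(ed, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
    ## keep the node universe even when some nodes are isolated
    writeLines(c(readLines(path),
                 paste0("#nodes\t", paste(g$nodes, collapse = "\t"))),
               path)
  } else {
    q <- function(x) paste0("\"", x, "\"")
    lines <- c("digraph pdag {")
    for (nd in g$nodes) lines <- c(lines, paste0("  ", q(nd), ";"))
    for (r in seq_len(nrow(g$edges))) {
      a <- q(g$nodes[g$edges$from[r]]); b <- q(g$nodes[g$edges$to[r]])
      style <- if (g$edges$mark[r] == "directed") "" else " [dir=none]"
      lines <- c(lines, paste0("  ", a, " -> ", b, style, ";"))
    }
    lines <- c(lines, "}")
    writeLines(lines, path)
  }
  invisible(path)
}

#' @rdname export_graph
#' @export
read_pdag_tsv <- function(path) {
  lines <- readLines(path)
  nl <- grep("^#nodes\t", lines)
  nodes <- NULL
  if (length(nl)) {
    nodes <- strsplit(sub("^#nodes\t", "", lines[nl[1L]]), "\t")[[1L]]
    lines <- lines[-nl]
  }
  ed <- utils::read.table(text = lines, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (is.null(nodes)) nodes <- sort(unique(c(ed$from, ed$to)))
  hpd <- if (nrow(ed)) ed$hpd_content[1L] else NA_real_
  pdag(nodes,
       data.frame(from = match(ed$from, nodes), to = match(ed$to, nodes),
                  mark = ed$mark, stringsAsFactors = FALSE),
       hpd_content = hpd)
}

unshielded_colliders <- function(g) {
  adj <- adjacency_list(g)
  dirm <- g$edges[g$edges$mark == "directed", , drop = FALSE]
  out <- character(0)
  n <- length(g$nodes)
  for (m in seq_len(n)) {
    into <- dirm$from[dirm$to == m]
    if (length(into) < 2L) next
    prs <- utils::combn(sort(into), 2L)
    for (q in seq_len(ncol(prs))) {
      i <- prs[1L, q]; j <- prs[2L, q]
      if (!(j %in% adj[[i]]))
        out <- c(out, paste0(g$nodes[i], "->", g$nodes[m], "<-",
                             g$nodes[j]))
    }
  }
  out
}

#' Orient part of a PDAG from prior knowledge
#'
#' Applies a declared ordered trait chain (first element causally
#' upstream) to the undirected edges of a PDAG, then verifies the result
#' introduces neither directed cycles nor unshielded colliders that the
#' data-driven search did not support.
#'
#' @param g a \code{pdag}.
#' @param chain character vector of trait names in causal order; each
#'   consecutive pair must be an edge of the graph.
#' @return the oriented \code{pdag}.
#' @export
orient_by_prior_knowledge <- function(g, chain) {
  stopifnot(inherits(g, "pdag"))
  idx <- match(chain, g$nodes)
  if (anyNA(idx)) stop("unknown trait(s) in prior-knowledge chain: ",
                       paste(chain[is.na(idx)], collapse = ", "))
  edges <- g$edges
  before <- unshielded_colliders(g)
  for (q in seq_len(length(idx) - 1L)) {
    a <- idx[q]; b <- idx[q + 1L]
    r <- edge_row(g, a, b)
    if (length(r) != 1L)
      stop("prior-knowledge edge absent from the graph: ",
           chain[q], " -> ", chain[q + 1L])
    if (edges$mark[r] == "directed" &&
        !(edges$from[r] == a && edges$to[r] == b))
      stop("prior-knowledge orientation conflicts with the data-driven ",
           "direction of edge ", chain[q], " -> ", chain[q + 1L])
    edges$from[r] <- a; edges$to[r] <- b; edges$mark[r] <- "directed"
  }
  out <- tryCatch(pdag(g$nodes, edges, hpd_content = g$hpd_content),
                  error = function(e)
                    stop("prior-knowledge orientation creates a cycle: ",
                         conditionMessage(e)))
  new_coll <- setdiff(unshielded_colliders(out), before)
  if (length(new_coll))
    stop("prior-knowledge orientation creates unshielded collider(s) ",
         "not supported by the search: ", paste(new_coll, collapse = "; "))
  out
}

#' Assemble a pipeline configuration
#'
#' @param design a [study_design()] (or NULL when phenotype/pedigree
#'   paths are supplied).
#' @param truth a [simulation_truth()] used when simulating.
#' @param phenotypes_path,pedigree_path input files, used instead of
#'   simulation when both are given.
#' @param traits trait columns to analyse (default: from the data).
#' @param k latent factors for the multi-trait fit (default: PCA choice).
#' @param hpd_contents strictly decreasing HPD ladder.
#' @param prior_knowledge ordered trait chain used to orient the
#'   selected network before the SEM stage (NULL skips SEM).
#' @param variance_floor,wilmink_exponent,chains,iters,burn_in,thin,seed
#'   model and MCMC settings shared by both fits.
#' @param sem_k latent factors of the SEM direct-genetic covariance.
#' @return object of class \code{pipeline_config}.
#' @export
pipeline_config <- function(design = study_design(), truth = default_truth(),
                            phenotypes_path = NULL, pedigree_path = NULL,
                            traits = NULL, k = NULL,
                            hpd_contents = c(0.95, 0.90, 0.85, 0.80),
                            prior_knowledge = NULL, variance_floor = 0.02,
                            wilmink_exponent = 0.05, chains = 4L,
                            iters = 20000L, burn_in = 5000L, thin = 10L,
                            sem_k = 2L, seed = 1L) {
  if (any(diff(hpd_contents) >= 0) || any(hpd_contents <= 0) ||
      any(hpd_contents >= 1))
    stop("hpd_contents must be strictly decreasing fractions in (0, 1)")
  base::structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) data, fit the multi-trait model, run the IC search
#' at every HPD content, orient the selected network by prior knowledge,
#' fit the SEM, and compare the two models. All artifacts are written
#' under \code{dir}: the data set, posterior covariance samples (flat
#' CSV), one PDAG (TSV + DOT) per HPD content, the IC decision audit
#' log, the model-comparison report and a manifest.
#'
#' @param config a [pipeline_config()].
#' @param dir output directory.
#' @return list with the fitted objects, PDAGs and comparison, invisibly
#'   alongside the artifact paths in \code{$paths}.
#' @export
run_pipeline <- function(config, dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()

  ## ---- data
  if (!is.null(config$phenotypes_path) && !is.null(config$pedigree_path)) {
    phen <- utils::read.csv(config$phenotypes_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    ped <- read_pedigree(config$pedigree_path)
    truth <- NULL
  } else {
    sim <- simulate_dataset(config$design, config$truth, seed = config$seed)
    phen <- sim$phenotypes
    ped <- sim$pedigree
    truth <- sim$truth
    write_simulation(sim, file.path(dir, "data"))
    paths$data <- file.path(dir, "data")
  }
  traits <- config$traits
  if (is.null(traits))
    traits <- setdiff(names(phen)[vapply(phen, is.numeric, NA)],
                      covariate_cols)

  ## ---- multi-trait fit
  mtm <- fit_mtm(phen, ped, traits = traits, k = config$k,
                 variance_floor = config$variance_floor,
                 wilmink_exponent = config$wilmink_exponent,
                 chains = config$chains, iters = config$iters,
                 burn_in = config$burn_in, thin = config$thin,
                 seed = config$seed)
  paths$posteriors <- file.path(dir, "posterior_covariances.csv")
  write_posterior_csv(mtm$samples, paths$posteriors)

  ## ---- IC search
  nets <- ic_search(mtm$samples, contents = config$hpd_contents)
  ppc <- attr(nets, "ppc")
  paths$pdags <- character(0)
  for (nm in names(nets)) {
    tsv <- file.path(dir, paste0("network_", nm, ".tsv"))
    dot <- file.path(dir, paste0("network_", nm, ".dot"))
    export_graph(nets[[nm]], tsv, "tsv")
    export_graph(nets[[nm]], dot, "dot")
    paths$pdags <- c(paths$pdags, tsv, dot)
  }
  paths$audit <- file.path(dir, "ic_decisions.csv")
  write_ic_audit(ppc, config$hpd_contents[1L], paths$audit)

  ## ---- SEM on the prior-knowledge-oriented network
  sem <- comparison <- oriented <- NULL
  if (!is.null(config$prior_knowledge)) {
    oriented <- orient_by_prior_knowledge(nets[[1L]],
                                          config$prior_knowledge)
    struct <- chain_structure(config$prior_knowledge)
    sem <- fit_sem(phen, ped, struct, k = config$sem_k,
                   variance_floor = config$variance_floor,
                   wilmink_exponent = config$wilmink_exponent,
                   chains = config$chains, iters = config$iters,
                   burn_in = config$burn_in, thin = config$thin,
                   seed = config$seed + 1L)
    mtm_sub <- if (identical(sort(config$prior_knowledge), sort(traits)))
      mtm
    else
      fit_mtm(phen, ped, traits = config$prior_knowledge,
              k = min(config$sem_k, length(config$prior_knowledge) - 1L),
              variance_floor = config$variance_floor,
              wilmink_exponent = config$wilmink_exponent,
              chains = config$chains, iters = config$iters,
              burn_in = config$burn_in, thin = config$thin,
              seed = config$seed + 2L)
    comparison <- compare_models(mtm_sub, sem)
    paths$comparison <- file.path(dir, "model_comparison.csv")
    utils::write.csv(comparison$report, paths$comparison,
                     row.names = FALSE)
    tsvp <- file.path(dir, "network_selected_oriented.tsv")
    export_graph(oriented, tsvp, "tsv")
    paths$pdags <- c(paths$pdags, tsvp)
  }

  ## ---- manifest
  cfg_repr <- config
  cfg_repr$design <- unclass(cfg_repr$design)
  cfg_repr$truth <- if (!is.null(truth))
    list(traits = truth$traits, lambda = as.vector(truth$lambda),
         G0_star = as.vector(truth$G0_star), Psi0 = truth$Psi0)
  cfg_yaml <- yaml::as.yaml(lapply(cfg_repr, function(x)
    if (is.function(x)) NULL else x))
  counts <- count_ic_tests(length(traits))
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(cfg_yaml),
    traits = traits,
    n_records = nrow(phen),
    n_animals = nrow(ped),
    ic_tests = counts,
    n_partial_correlation_series = nrow(ppc$index),
    hpd_contents = config$hpd_contents,
    pdags = basename(paths$pdags),
    dic_mtm = mtm$dic$dic,
    dic_sem = if (!is.null(sem)) sem$dic$dic else NA,
    r_version = as.character(getRversion()))
  paths$manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, paths$manifest)

  invisible(list(mtm = mtm, networks = nets, oriented = oriented,
                 sem = sem, comparison = comparison, truth = truth,
                 manifest = manifest, paths = paths))
}

config_hash <- function(txt) {
  tf <- tempfile()
  writeLines(txt, tf)
  on.exit(unlink(tf))
  unname(tools::md5sum(tf))
}

write_posterior_csv <- function(samples, path) {
  arr_list <- list(G0 = samples$G0, R0 = samples$R0)
  rows <- list()
  for (nm in names(arr_list)) {
    arr <- arr_list[[nm]]
    if (is.null(arr)) next
    t <- dim(arr)[1L]
    tn <- dimnames(arr)[[1L]]
    if (is.null(tn)) tn <- paste0("T", seq_len(t))
    for (i in seq_len(t)) for (j in i:t) {
      rows[[length(rows) + 1L]] <- data.frame(
        chain = if (is.null(samples$chain)) 1L else samples$chain,
        iter = if (is.null(samples$iter)) seq_len(dim(arr)[3L])
               else samples$iter,
        param = paste0(nm, "[", tn[i], ",", tn[j], "]"),
        value = arr[i, j, ])
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
}

write_ic_audit <- function(ppc, content, path) {
  lo <- hi <- numeric(nrow(ppc$index))
  for (r in seq_len(nrow(ppc$index))) {
    d <- ppc$draws[r, ]
    d <- d[is.finite(d)]
    h <- if (length(d) >= 10L) hpd_interval(d, content)
         else c(NA_real_, NA_real_)
    lo[r] <- h[1L]; hi[r] <- h[2L]
  }
  audit <- data.frame(
    i = ppc$traits[ppc$index$i], j = ppc$traits[ppc$index$j],
    subset = vapply(ppc$subsets, function(S)
      paste(ppc$traits[S], collapse = "|"), ""),
    hpd_lo = lo, hpd_hi = hi,
    decision = ifelse(lo > 0 | hi < 0, "dependent", "independent"))
  utils::write.csv(audit, path, row.names = FALSE)
}
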
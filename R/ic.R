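#' Partial correlation from a covariance matrix
#'
#' Computes the correlation between variables \code{i} and \code{j}
#' conditional on the set \code{S}, from the joint covariance matrix.
#' The submatrix over \code{c(i, j, S)} is inverted and the partial
#' correlation read off the precision matrix as
#' \eqn{-\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}}. With \code{S} empty
#' this is the ordinary (marginal) correlation. Under multivariate
#' normality a zero partial correlation is equivalent to conditional
#' independence, which is what the IC algorithm tests.
#'
#' @param sigma covariance (or correlation) matrix.
#' @param i,j variable indices or names; distinct, not in \code{S}.
#' @param S conditioning set (possibly empty vector of indices/names).
#' @return partial correlation in \[-1, 1\].
#' @export
partial_correlation <- function(sigma, i, j, S = integer(0)) {
  v <- resolve_vars(sigma, i, j, S)
  sub <- sigma[v, v, drop = FALSE]
  kap <- kappa(sub, exact = FALSE)
  om <- tryCatch(solve(sub), error = function(e) NULL)
  if (is.null(om) || !all(is.finite(om))) {
    stop("singular covariance submatrix (condition number ",
         format(kap, digits = 3), ") for pair (", i, ",", j, ") given {",
         paste(S, collapse = ","), "}")
  }
  r <- -om[1L, 2L] / sqrt(om[1L, 1L] * om[2L, 2L])
  max(-1, min(1, r))
}

resolve_vars <- function(sigma, i, j, S) {
  nm <- colnames(sigma)
  tovec <- function(x) {
    if (is.character(x)) match(x, nm) else as.integer(x)
  }
  v <- c(tovec(i), tovec(j), if (length(S)) tovec(S) else integer(0))
  if (anyNA(v)) stop("unknown variable reference")
  if (anyDuplicated(v)) stop("i, j and S must be distinct")
  v
}

#' Number of IC conditional-independence tests
#'
#' For \code{t} traits there are \code{t(t-1)/2} distinct pairs and, for
#' each pair, \code{2^(t-2)} subsets of the remaining traits to condition
#' on, so the full IC plan evaluates \code{t(t-1)/2 * 2^(t-2)} partial
#' correlations per posterior covariance sample.
#'
#' @param t number of traits (>= 2).
#' @return list with \code{n_pairs}, \code{n_subsets_per_pair},
#'   \code{n_total}.
#' @export
count_ic_tests <- function(t) {
  if (!is.numeric(t) || length(t) != 1L || t < 2)
    stop("t must be a single integer >= 2")
  t <- as.integer(t)
  n_pairs <- t * (t - 1L) / 2
  n_sub <- 2^(t - 2L)
  list(n_pairs = n_pairs, n_subsets_per_pair = n_sub,
       n_total = n_pairs * n_sub)
}

## Enumerate the test plan: every unordered pair (i, j) and every subset
## of the remaining variables up to max_cond_size.
ic_plan <- function(t, max_cond_size = t - 2L) {
  pairs <- utils::combn(t, 2L)
  plan <- list()
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1L, p]; j <- pairs[2L, p]
    rest <- setdiff(seq_len(t), c(i, j))
    subs <- list(integer(0))
    for (sz in seq_len(min(length(rest), max_cond_size))) {
      cmb <- utils::combn(seq_along(rest), sz)   # avoid combn's scalar rule
      subs <- c(subs, lapply(seq_len(ncol(cmb)),
                             function(q) rest[cmb[, q]]))
    }
    plan[[p]] <- list(i = i, j = j, subsets = subs)
  }
  plan
}

#' Posterior partial correlations over the full IC plan
#'
#' For every retained posterior sample of the residual covariance matrix
#' and every (pair, conditioning subset) in the plan, one partial
#' correlation draw is computed. The resulting draws are the posterior
#' distributions on which the HPD dependence decisions are made.
#'
#' @param samples a \code{posterior_covariances} object (see
#'   [posterior_covariances()]) or a 3-d array \code{t x t x S} of
#'   covariance samples.
#' @param max_cond_size cap on conditioning-set size (default \code{t-2},
#'   i.e. the full enumeration).
#' @return object of class \code{posterior_partial_correlations}: a list
#'   with \code{index} (data frame: pair, subset label), \code{draws}
#'   (matrix, n_series x n_samples), \code{plan}, \code{traits},
#'   \code{n_excluded} (draws dropped because a submatrix was singular).
#' @export
posterior_partial_correlations <- function(samples, max_cond_size = NULL) {
  arr <- as_cov_array(samples)
  t <- dim(arr)[1L]
  ns <- dim(arr)[3L]
  if (ns < 30L)
    warning("only ", ns, " posterior covariance samples; HPD decisions ",
            "will be unstable below ~30")
  if (is.null(max_cond_size)) max_cond_size <- t - 2L
  plan <- ic_plan(t, max_cond_size)
  traits <- dimnames(arr)[[1L]]
  if (is.null(traits)) traits <- paste0("T", seq_len(t))

  nser <- sum(vapply(plan, function(p) length(p$subsets), 1L))
  draws <- matrix(NA_real_, nser, ns)
  idx_i <- idx_j <- integer(nser)
  idx_S <- vector("list", nser)
  n_excluded <- 0L
  row <- 0L
  for (p in plan) {
    for (S in p$subsets) {
      row <- row + 1L
      idx_i[row] <- p$i; idx_j[row] <- p$j; idx_S[[row]] <- S
    }
  }
  for (s in seq_len(ns)) {
    sg <- arr[, , s]
    row <- 0L
    for (p in plan) {
      for (S in p$subsets) {
        row <- row + 1L
        val <- tryCatch(partial_correlation(sg, p$i, p$j, S),
                        error = function(e) NA_real_)
        if (is.na(val)) n_excluded <- n_excluded + 1L
        draws[row, s] <- val
      }
    }
  }
  structure(list(index = data.frame(i = idx_i, j = idx_j,
                                    subset = vapply(idx_S, paste, "",
                                                    collapse = ","),
                                    stringsAsFactors = FALSE),
                 subsets = idx_S, draws = draws, traits = traits,
                 n_samples = ns, n_excluded = n_excluded),
            class = "posterior_partial_correlations")
}

as_cov_array <- function(samples) {
  if (inherits(samples, "posterior_covariances")) return(samples$R0)
  if (is.array(samples) && length(dim(samples)) == 3L) return(samples)
  if (is.list(samples)) {
    t <- nrow(samples[[1L]])
    arr <- array(unlist(samples), dim = c(t, t, length(samples)),
                 dimnames = c(dimnames(samples[[1L]]), list(NULL)))
    return(arr)
  }
  stop("cannot interpret 'samples' as covariance samples")
}

#' Container for posterior covariance samples
#'
#' Bundles posterior draws of the genetic (\code{G0}) and residual
#' (\code{R0}) covariance matrices, as emitted by [fit_mtm()] or built
#' from any other source of covariance samples.
#'
#' @param R0 \code{t x t x S} array of residual covariance draws.
#' @param G0 optional matching array of genetic covariance draws.
#' @param chain,iter optional integer labels per draw.
#' @return object of class \code{posterior_covariances}.
#' @export
posterior_covariances <- function(R0, G0 = NULL, chain = NULL, iter = NULL) {
  stopifnot(length(dim(R0)) == 3L, dim(R0)[1L] == dim(R0)[2L])
  structure(list(R0 = R0, G0 = G0, chain = chain, iter = iter),
            class = "posterior_covariances")
}

#' @export
print.posterior_covariances <- function(x, ...) {
  d <- dim(x$R0)
  cat("Posterior covariance samples:", d[3L], "draws of", d[1L], "x",
      d[2L], "matrices", if (!is.null(x$G0)) "(G0 and R0)" else "(R0 only)",
      "\n")
  invisible(x)
}

#' Highest posterior density interval (Chen-Shao)
#'
#' The shortest interval containing \code{ceiling(content * N)} of the
#' sorted draws. Ties between equally short windows are broken in favour
#' of the lowest window start.
#'
#' @param draws numeric sample vector (>= 10 draws).
#' @param content interval probability content in (0, 1\].
#' @return numeric \code{c(lo, hi)}.
#' @export
hpd_interval <- function(draws, content = 0.95) {
  draws <- draws[is.finite(draws)]
  n <- length(draws)
  if (n < 10L) stop("need at least 10 draws for an HPD interval")
  if (!is.numeric(content) || content <= 0 || content > 1)
    stop("content must be in (0, 1]")
  x <- sort(draws)
  m <- ceiling(content * n)
  if (m >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m)          # window [s, s + m] holds m + 1 points
  widths <- x[starts + m] - x[starts]
  s <- starts[which.min(widths)]    # which.min takes the first (lowest) tie
  c(x[s], x[s + m])
}

hpd_excludes_zero <- function(draws, content) {
  h <- hpd_interval(draws, content)
  h[1L] > 0 || h[2L] < 0
}

#' IC step 1: skeleton from posterior partial correlations
#'
#' An edge is placed between traits i and j if and only if, for every
#' conditioning subset of the other traits, the HPD interval of the
#' posterior partial correlation excludes zero (the pair is declared
#' dependent conditionally on every possible set). For pairs left
#' non-adjacent, every subset whose HPD covered zero is recorded as a
#' separating set; those records drive the collider search of step 2.
#'
#' @param ppc a \code{posterior_partial_correlations} object.
#' @param content HPD probability content (default 0.95).
#' @return list with \code{graph} (a \code{pdag} with undirected edges)
#'   and \code{sepsets} (per non-adjacent pair, the list of separating
#'   subsets).
#' @export
ic_skeleton <- function(ppc, content = 0.95) {
  stopifnot(inherits(ppc, "posterior_partial_correlations"))
  t <- length(ppc$traits)
  key <- paste(ppc$index$i, ppc$index$j, sep = "-")
  edges <- list()
  sepsets <- list()
  for (k in unique(key)) {
    rows <- which(key == k)
    i <- ppc$index$i[rows[1L]]; j <- ppc$index$j[rows[1L]]
    excl <- vapply(rows, function(r) {
      d <- ppc$draws[r, ]
      d <- d[is.finite(d)]
      if (length(d) < 10L) return(NA)
      hpd_excludes_zero(d, content)
    }, NA)
    if (all(excl, na.rm = TRUE) && !anyNA(excl)) {
      edges[[length(edges) + 1L]] <- c(i, j)
    } else {
      cover <- rows[!vapply(seq_along(rows), function(q)
        isTRUE(excl[q]), NA)]
      sepsets[[k]] <- ppc$subsets[cover]
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(integer(0), 0L, 2L)
  g <- pdag(ppc$traits,
            edges = data.frame(from = em[, 1L], to = em[, 2L],
                               mark = rep("undirected", nrow(em)),
                               stringsAsFactors = FALSE),
            hpd_content = content)
  list(graph = g, sepsets = sepsets)
}

#' Construct a partially directed acyclic graph (PDAG)
#'
#' @param nodes character vector of trait names (or a count).
#' @param edges data frame with integer columns \code{from}, \code{to}
#'   and character column \code{mark} (\code{"undirected"} or
#'   \code{"directed"}, the latter meaning from -> to).
#' @param hpd_content provenance: the HPD content that produced the graph.
#' @return object of class \code{pdag}.
#' @export
pdag <- function(nodes, edges = NULL, hpd_content = NA_real_) {
  if (is.numeric(nodes) && length(nodes) == 1L)
    nodes <- paste0("T", seq_len(nodes))
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        mark = character(0), stringsAsFactors = FALSE)
  }
  stopifnot(all(edges$mark %in% c("undirected", "directed")))
  if (any(edges$from == edges$to)) stop("self-edges are not allowed")
  pk <- pmin(edges$from, edges$to) * 1000L + pmax(edges$from, edges$to)
  if (anyDuplicated(pk)) stop("at most one edge per pair of nodes")
  g <- structure(list(nodes = nodes, edges = edges,
                      hpd_content = hpd_content), class = "pdag")
  dir <- edges[edges$mark == "directed", , drop = FALSE]
  if (nrow(dir) && has_directed_cycle(length(nodes), dir))
    stop("directed part of the PDAG contains a cycle")
  g
}

has_directed_cycle <- function(n, dir_edges) {
  indeg <- integer(n)
  adj <- vector("list", n)
  for (r in seq_len(nrow(dir_edges))) {
    a <- dir_edges$from[r]; b <- dir_edges$to[r]
    adj[[a]] <- c(adj[[a]], b)
    indeg[b] <- indeg[b] + 1L
  }
  queue <- which(indeg == 0L); seen <- 0L
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]; seen <- seen + 1L
    for (b in adj[[i]]) {
      indeg[b] <- indeg[b] - 1L
      if (indeg[b] == 0L) queue <- c(queue, b)
    }
  }
  seen < n
}

adjacency_list <- function(g) {
  n <- length(g$nodes)
  adj <- vector("list", n)
  for (r in seq_len(nrow(g$edges))) {
    a <- g$edges$from[r]; b <- g$edges$to[r]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

edge_row <- function(g, a, b) {
  which((g$edges$from == a & g$edges$to == b) |
        (g$edges$from == b & g$edges$to == a))
}

#' @export
print.pdag <- function(x, ...) {
  cat("PDAG over", length(x$nodes), "traits")
  if (!is.na(x$hpd_content))
    cat(" (HPD content ", format(100 * x$hpd_content), "%)", sep = "")
  cat(":", nrow(x$edges), "edges\n")
  if (nrow(x$edges)) {
    for (r in seq_len(nrow(x$edges))) {
      a <- x$nodes[x$edges$from[r]]; b <- x$nodes[x$edges$to[r]]
      sym <- if (x$edges$mark[r] == "directed") "->" else "--"
      cat("  ", a, sym, b, "\n")
    }
  }
  invisible(x)
}

#' @export
plot.pdag <- function(x, ...) {
  n <- length(x$nodes)
  th <- seq(0, 2 * pi, length.out = n + 1L)[seq_len(n)]
  px <- cos(th); py <- sin(th)
  graphics::plot(px, py, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3),
                 axes = FALSE, xlab = "", ylab = "", pch = 19, ...)
  graphics::text(1.17 * px, 1.17 * py, x$nodes, cex = 0.9)
  for (r in seq_len(nrow(x$edges))) {
    a <- x$edges$from[r]; b <- x$edges$to[r]
    shrink <- 0.07
    dx <- px[b] - px[a]; dy <- py[b] - py[a]
    len <- sqrt(dx^2 + dy^2)
    x0 <- px[a] + shrink * dx / len; y0 <- py[a] + shrink * dy / len
    x1 <- px[b] - shrink * dx / len; y1 <- py[b] - shrink * dy / len
    if (x$edges$mark[r] == "directed") {
      graphics::arrows(x0, y0, x1, y1, length = 0.1)
    } else {
      graphics::segments(x0, y0, x1, y1)
    }
  }
  invisible(x)
}

#' IC step 2: orient unshielded colliders
#'
#' For every unshielded triple i - m - j (i and j non-adjacent but both
#' adjacent to m), the triple is oriented as a collider i -> m <- j if
#' and only if m belongs to none of the recorded separating sets of the
#' pair (i, j). Conflicting orientation demands on a single edge abort
#' with a report of the offending triples rather than being resolved
#' silently.
#'
#' @param skeleton output of [ic_skeleton()] (list with \code{graph} and
#'   \code{sepsets}), or a \code{pdag} plus explicit \code{sepsets}.
#' @param sepsets separating-set record if \code{skeleton} is a
#'   \code{pdag}.
#' @return a \code{pdag} with collider edges marked directed.
#' @export
orient_colliders <- function(skeleton, sepsets = NULL) {
  if (is.list(skeleton) && !inherits(skeleton, "pdag")) {
    g <- skeleton$graph; sepsets <- skeleton$sepsets
  } else {
    g <- skeleton
  }
  stopifnot(inherits(g, "pdag"))
  adj <- adjacency_list(g)
  n <- length(g$nodes)
  want <- list()  # directed demands: list of c(from, to, triple label)
  for (m in seq_len(n)) {
    nb <- adj[[m]]
    if (length(nb) < 2L) next
    prs <- utils::combn(sort(nb), 2L)
    for (q in seq_len(ncol(prs))) {
      i <- prs[1L, q]; j <- prs[2L, q]
      if (j %in% adj[[i]]) next               # shielded
      key <- paste(min(i, j), max(i, j), sep = "-")
      ss <- sepsets[[key]]
      in_any <- any(vapply(ss, function(S) m %in% S, NA))
      if (is.na(in_any)) in_any <- FALSE      # no recorded sets
      if (!in_any) {
        lab <- paste0(g$nodes[i], "->", g$nodes[m], "<-", g$nodes[j])
        want[[length(want) + 1L]] <- list(from = i, to = m, triple = lab)
        want[[length(want) + 1L]] <- list(from = j, to = m, triple = lab)
      }
    }
  }
  edges <- g$edges
  for (w in want) {
    r <- edge_row(g, w$from, w$to)
    cur <- edges$mark[r]
    if (cur == "directed" &&
        !(edges$from[r] == w$from && edges$to[r] == w$to)) {
      conflicts <- vapply(want, function(z) z$triple, "")
      stop("conflicting collider orientations: ",
           paste(unique(conflicts), collapse = "; "))
    }
    edges$from[r] <- w$from; edges$to[r] <- w$to
    edges$mark[r] <- "directed"
  }
  pdag(g$nodes, edges, hpd_content = g$hpd_content)
}

#' IC step 3: propagate orientations
#'
#' Applies to a fixpoint the two propagation rules that follow from
#' forbidding new unshielded colliders and directed cycles:
#' R1: if a -> b - c with a, c non-adjacent, orient b -> c;
#' R2: if a -> b -> c with a - c undirected, orient a -> c.
#'
#' @param g a \code{pdag} whose directed part is acyclic.
#' @return the closed \code{pdag}.
#' @export
propagate_orientations <- function(g) {
  stopifnot(inherits(g, "pdag"))
  repeat {
    changed <- FALSE
    adj <- adjacency_list(g)
    edges <- g$edges
    dirm <- edges[edges$mark == "directed", , drop = FALSE]
    und  <- edges[edges$mark == "undirected", , drop = FALSE]
    orient <- function(a, b) {
      r <- edge_row(g, a, b)
      if (edges$mark[r] == "undirected") {
        edges$from[r] <<- a; edges$to[r] <<- b
        edges$mark[r] <<- "directed"
        changed <<- TRUE
      }
    }
    ## R1
    for (r in seq_len(nrow(dirm))) {
      a <- dirm$from[r]; b <- dirm$to[r]
      for (q in seq_len(nrow(und))) {
        cands <- c(und$from[q], und$to[q])
        if (b %in% cands) {
          cc <- setdiff(cands, b)
          if (length(cc) == 1L && cc != a && !(cc %in% adj[[a]]))
            orient(b, cc)
        }
      }
    }
    g2 <- pdag(g$nodes, edges, hpd_content = g$hpd_content)
    ## R2 on the updated edge set
    edges <- g2$edges
    dirm <- edges[edges$mark == "directed", , drop = FALSE]
    for (r in seq_len(nrow(dirm))) {
      a <- dirm$from[r]; b <- dirm$to[r]
      for (q in seq_len(nrow(dirm))) {
        if (dirm$from[q] == b) {
          cc <- dirm$to[q]
          rr <- edge_row(g2, a, cc)
          if (length(rr) == 1L && g2$edges$mark[rr] == "undirected") {
            edges$from[rr] <- a; edges$to[rr] <- cc
            edges$mark[rr] <- "directed"
            changed <- TRUE
          }
        }
      }
    }
    g <- pdag(g$nodes, edges, hpd_content = g$hpd_content)
    if (!changed) break
  }
  g
}

#' Full IC search on posterior covariance samples
#'
#' Runs the three IC steps (skeleton, collider orientation, orientation
#' propagation) at one or more HPD interval contents. Because a narrower
#' interval still excludes zero whenever a wider one does, lowering the
#' content can only add edges; the standard relaxation ladder
#' (95, 90, 85, 80%) is therefore monotone.
#'
#' @param samples \code{posterior_covariances} (or covariance array);
#'   the residual covariance draws are used.
#' @param contents numeric vector of HPD contents, strictly decreasing.
#' @param max_cond_size cap on conditioning-set size; default full plan.
#' @return a named list of \code{pdag} objects, one per content, with the
#'   shared \code{posterior_partial_correlations} attached as attribute
#'   \code{"ppc"}.
#' @export
ic_search <- function(samples, contents = c(0.95, 0.90, 0.85, 0.80),
                      max_cond_size = NULL) {
  if (any(diff(contents) >= 0) || any(contents <= 0) || any(contents >= 1))
    stop("contents must be strictly decreasing fractions in (0, 1)")
  ppc <- posterior_partial_correlations(samples, max_cond_size)
  out <- lapply(contents, function(cc) {
    sk <- ic_skeleton(ppc, cc)
    g <- orient_colliders(sk)
    propagate_orientations(g)
  })
  names(out) <- paste0("hpd", formatC(100 * contents, format = "d"))
  attr(out, "ppc") <- ppc
  out
}
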
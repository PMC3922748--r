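#' Parse a pedigree into topological (parents-before-offspring) order
#'
#' A pedigree is a table of animal, sire and dam identifiers. Unknown
#' parents are coded with a configurable missing code (default \code{"0"},
#' empty string or \code{NA}). The returned object lists every animal in
#' an order in which each parent precedes all of its offspring, which is
#' the order required by the tabular relationship-matrix construction and
#' by gene-dropping simulation.
#'
#' Parents that are referenced but never defined as animals themselves are
#' auto-inserted as founders with a warning.
#'
#' @param records data frame (or coercible) with columns
#'   \code{animal}, \code{sire}, \code{dam}.
#' @param missing character vector of codes meaning "parent unknown".
#' @return An object of class \code{pedigree}: a data frame with character
#'   columns \code{animal}, \code{sire}, \code{dam} (\code{NA} = unknown),
#'   in topological order, with attribute \code{generation_depth} (longest
#'   ancestral path, founders = depth 0 so a founder-only pedigree has
#'   depth 0).
#' @seealso [read_pedigree()], [nrm()]
#' @export
parse_pedigree <- function(records, missing = c("0", "", "NA")) {
  records <- as.data.frame(records)
  if (nrow(records) == 0L) {
    ped <- data.frame(animal = character(), sire = character(),
                      dam = character(), stringsAsFactors = FALSE)
    class(ped) <- c("pedigree", "data.frame")
    attr(ped, "generation_depth") <- 0L
    return(ped)
  }
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(records))) {
    stop("pedigree table must have columns 'animal', 'sire', 'dam'")
  }
  an <- as.character(records$animal)
  si <- as.character(records$sire)
  da <- as.character(records$dam)
  si[si %in% missing | is.na(si)] <- NA_character_
  da[da %in% missing | is.na(da)] <- NA_character_
  if (anyDuplicated(an)) {
    stop("duplicate animal id(s): ",
         paste(unique(an[duplicated(an)]), collapse = ", "))
  }
  if (any(!is.na(si) & si == an) || any(!is.na(da) & da == an)) {
    bad <- an[(!is.na(si) & si == an) | (!is.na(da) & da == an)][1L]
    stop("pedigree cycle detected involving animal '", bad, "'")
  }
  parents <- setdiff(stats::na.omit(c(si, da)), an)
  if (length(parents)) {
    warning("parent id(s) never defined as animals, inserted as founders: ",
            paste(parents, collapse = ", "))
    an <- c(parents, an)
    si <- c(rep(NA_character_, length(parents)), si)
    da <- c(rep(NA_character_, length(parents)), da)
  }

  ## Kahn's algorithm; depth = longest path from a founder
  n <- length(an)
  idx <- seq_len(n)
  names(idx) <- an
  sid <- ifelse(is.na(si), 0L, idx[si])
  did <- ifelse(is.na(da), 0L, idx[da])
  indeg <- integer(n)
  for (p in c(sid, did)) if (p > 0L) indeg[p] <- indeg[p]  # no-op, clarity
  ## children lists
  kids <- vector("list", n)
  indeg <- (sid > 0L) + (did > 0L)
  for (i in idx) {
    if (sid[i] > 0L) kids[[sid[i]]] <- c(kids[[sid[i]]], i)
    if (did[i] > 0L) kids[[did[i]]] <- c(kids[[did[i]]], i)
  }
  depth <- integer(n)
  queue <- integer(n)
  roots <- which(indeg == 0L)
  nq <- length(roots)
  queue[seq_len(nq)] <- roots
  head <- 0L
  while (head < nq) {
    head <- head + 1L
    i <- queue[head]
    for (ch in kids[[i]]) {
      depth[ch] <- max(depth[ch], depth[i] + 1L)
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) {
        nq <- nq + 1L
        queue[nq] <- ch
      }
    }
  }
  if (nq < n) {
    bad <- an[setdiff(idx, queue[seq_len(nq)])][1L]
    stop("pedigree cycle detected involving animal '", bad, "'")
  }
  ## stable order: by depth, then original appearance
  ord <- order(depth, idx)
  ped <- data.frame(animal = an[ord], sire = si[ord], dam = da[ord],
                    stringsAsFactors = FALSE)
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  attr(ped, "generation_depth") <- max(depth)
  ped
}

#' Read a pedigree file
#'
#' Reads a comma- or tab-delimited pedigree with header
#' \code{animal,sire,dam} and returns it parsed and topologically ordered.
#'
#' @param path file path.
#' @param missing codes meaning "parent unknown"; see [parse_pedigree()].
#' @param sep field separator; \code{""} guesses from the header line.
#' @return a \code{pedigree} object.
#' @export
read_pedigree <- function(path, missing = c("0", "", "NA"), sep = "") {
  if (identical(sep, "")) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character",
                           stringsAsFactors = FALSE)
  parse_pedigree(tab, missing = missing)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders, generation depth",
      attr(x, "generation_depth"), "\n")
  if (nrow(x)) print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

parent_indices <- function(ped) {
  idx <- seq_len(nrow(ped))
  names(idx) <- ped$animal
  cbind(sire = ifelse(is.na(ped$sire), 0L, idx[ped$sire]),
        dam  = ifelse(is.na(ped$dam),  0L, idx[ped$dam]))
}

#' Numerator (additive) relationship matrix
#'
#' Builds the additive genetic relationship matrix \eqn{A} of a pedigree
#' by the tabular method: for animal \eqn{i} with parents \eqn{s,d},
#' \eqn{A_{ij} = (A_{sj} + A_{dj})/2} for \eqn{j < i} and
#' \eqn{A_{ii} = 1 + A_{sd}/2}; an unknown parent contributes 0. The
#' diagonal therefore equals one plus the inbreeding coefficient, and
#' non-inbred founders have diagonal exactly 1.
#'
#' @param ped a \code{pedigree} (topologically ordered; [parse_pedigree()]
#'   guarantees this).
#' @return symmetric positive-definite matrix with dimnames = animal ids.
#' @export
nrm <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  if (n == 0L) return(A)
  par <- parent_indices(ped)
  for (i in seq_len(n)) {
    s <- par[i, 1L]; d <- par[i, 2L]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0L) A[s, j] else 0
      ad_ <- if (d > 0L) A[d, j] else 0
      A[i, j] <- A[j, i] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients of a pedigree
#'
#' Computed as diag(A) - 1 from the tabular relationship matrix. With at
#' most one ancestral generation all parents are unrelated founders, so
#' every F is exactly zero and the matrix is skipped.
#'
#' @param ped a \code{pedigree}.
#' @return named numeric vector of inbreeding coefficients F (diag(A) - 1).
#' @export
inbreeding <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (attr(ped, "generation_depth") <= 1L) {
    f <- rep(0, nrow(ped))
    names(f) <- ped$animal
    return(f)
  }
  diag(nrm(ped)) - 1
}

#' Prune a pedigree to a set of animals and their ancestors
#'
#' @param ped a \code{pedigree}.
#' @param keep animal ids whose ancestry must be retained.
#' @return the pruned \code{pedigree}.
#' @export
prune_pedigree <- function(ped, keep) {
  stopifnot(inherits(ped, "pedigree"))
  miss <- setdiff(keep, ped$animal)
  if (length(miss)) stop("unknown animal id(s): ", paste(miss, collapse = ", "))
  want <- ped$animal %in% keep
  par <- parent_indices(ped)
  for (i in rev(seq_len(nrow(ped)))) {
    if (want[i]) {
      if (par[i, 1L] > 0L) want[par[i, 1L]] <- TRUE
      if (par[i, 2L] > 0L) want[par[i, 2L]] <- TRUE
    }
  }
  parse_pedigree(as.data.frame(ped)[want, , drop = FALSE])
}

## Sparse inverse of A, built directly from pedigree structure and
## inbreeding coefficients (generalized-inverse decomposition
## A^-1 = (I - P)' D^-1 (I - P), P = half at parent positions, D =
## Mendelian-sampling variances). Internal: used only by the samplers,
## which need the precision matrix of pedigree-correlated effects.
ainverse_sparse <- function(ped, f = NULL) {
  n <- nrow(ped)
  if (is.null(f)) f <- inbreeding(ped)
  par <- parent_indices(ped)
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, v) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, v)
  }
  for (i in seq_len(n)) {
    s <- par[i, 1L]; d <- par[i, 2L]
    dm <- 1 -
      (if (s > 0L) 0.25 * (1 + f[s]) else 0) -
      (if (d > 0L) 0.25 * (1 + f[d]) else 0)
    w <- 1 / dm
    add(i, i, w)
    for (p in c(s, d)) {
      if (p > 0L) {
        add(i, p, -0.5 * w); add(p, i, -0.5 * w)
        add(p, p, 0.25 * w)
      }
    }
    if (s > 0L && d > 0L) {
      add(s, d, 0.25 * w); add(d, s, 0.25 * w)
      ## the two 0.25*w diagonal terms above already cover s,s and d,d
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$animal, ped$animal))
}
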
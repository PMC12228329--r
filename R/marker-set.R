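#' Marker gene set
#'
#' An assignment of a marker gene list to each cell type within a tissue.
#' The union of all per-type lists is the marker universe for the tissue;
#' a gene may appear under several cell types (which lowers its
#' specificity weight), but not twice under the same type.
#'
#' @param sets named list of character vectors: cell type -> marker genes.
#'   Names must be unique; every vector non-empty with no duplicates.
#' @param tissue tissue tag, e.g. `"hippocampus"`.
#' @param bounds length-2 integer vector `(k_min, k_max)` with the allowed
#'   per-type set sizes (default 1-30).
#' @param enforce_bounds if `TRUE`, error when any set size falls outside
#'   `bounds`.
#' @return an object of class `marker_set`.
#' @examples
#' S <- marker_set(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' marker_universe(S)
#' @export
marker_set <- function(sets, tissue = "unspecified", bounds = c(1L, 30L),
                       enforce_bounds = FALSE) {
  if (!is.list(sets) || length(sets) == 0L || is.null(names(sets)) ||
      anyDuplicated(names(sets)) || any(!nzchar(names(sets)))) {
    stop("`sets` must be a non-empty list uniquely named by cell type",
         call. = FALSE)
  }
  sets <- lapply(sets, as.character)
  sizes <- lengths(sets)
  if (any(sizes == 0L)) {
    stop("every cell type must have at least one marker gene; empty: ",
         paste(names(sets)[sizes == 0L], collapse = ", "), call. = FALSE)
  }
  dup <- vapply(sets, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    stop("duplicate genes within a cell type's marker list: ",
         paste(names(sets)[dup], collapse = ", "), call. = FALSE)
  }
  bounds <- as.integer(bounds)
  stopifnot(length(bounds) == 2L, bounds[1] >= 1L, bounds[2] >= bounds[1])
  if (enforce_bounds && (any(sizes < bounds[1]) || any(sizes > bounds[2]))) {
    stop("marker set sizes outside bounds [", bounds[1], ", ", bounds[2], "]",
         call. = FALSE)
  }
  structure(list(sets = sets, tissue = tissue, bounds = bounds),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> tissue = %s, %d cell types, %d genes in universe\n",
              x$tissue, length(x$sets), length(marker_universe(x))))
  for (nm in utils::head(names(x$sets), 8)) {
    g <- x$sets[[nm]]
    cat(sprintf("  %s (%d): %s%s\n", nm, length(g),
                paste(utils::head(g, 6), collapse = ", "),
                if (length(g) > 6) ", ..." else ""))
  }
  if (length(x$sets) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
length.marker_set <- function(x) length(x$sets)

#' Cell type names of a marker set
#' @param S a `marker_set`
#' @export
cell_types <- function(S) names(S$sets)

#' Marker universe (union of all per-type gene lists)
#' @param S a `marker_set`
#' @export
marker_universe <- function(S) unique(unlist(S$sets, use.names = FALSE))

#' Gene specificity weights
#'
#' For each gene `i` in the marker universe, let `n_i` be the number of
#' cell types whose marker list contains it. The specificity weight is
#' the min-max rescaled reciprocal occurrence
#' \deqn{\theta_i = \frac{1/n_i - \min_j(1/n_j)}{\max_j(1/n_j) - \min_j(1/n_j)},}
#' so genes marking fewer cell types score higher; the most shared gene
#' gets 0 and the most exclusive gets 1. When every gene occurs in the
#' same number of types the rescaling is degenerate (0/0) and all weights
#' are set to 1: every marker is treated as maximally informative.
#'
#' @param S a `marker_set`.
#' @return an object of class `specificity_weights`: list with `theta`
#'   and `occurrence`, both named by gene.
#' @examples
#' S <- marker_set(list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2"))
#' specificity_weights(S)$theta   # g1 = 1, g2 = 0, g3 = 1
#' @export
specificity_weights <- function(S) {
  stopifnot(inherits(S, "marker_set"))
  genes <- unlist(S$sets, use.names = FALSE)
  occ <- table(genes)
  n_i <- as.numeric(occ)
  names(n_i) <- names(occ)
  inv <- 1 / n_i
  rng <- range(inv)
  theta <- if (rng[1] == rng[2]) {
    stats::setNames(rep(1, length(inv)), names(inv))
  } else {
    (inv - rng[1]) / (rng[2] - rng[1])
  }
  structure(list(theta = theta, occurrence = n_i),
            class = "specificity_weights")
}

#' @export
print.specificity_weights <- function(x, ...) {
  cat(sprintf("<specificity_weights> %d genes, theta in [%.3g, %.3g]\n",
              length(x$theta), min(x$theta), max(x$theta)))
  invisible(x)
}

#' Remove one cell type's markers from a marker set
#'
#' Drops the marker list of cell type `type` entirely. Genes shared with
#' other cell types remain in those types; specificity weights must be
#' recomputed downstream since occurrence counts change. This is the
#' masking step of leave-one-cell-type-out evaluation.
#'
#' @param S a `marker_set`.
#' @param type a cell type name present in `S`.
#' @return a `marker_set` without `type`.
#' @export
mask_cell_type <- function(S, type) {
  stopifnot(inherits(S, "marker_set"))
  if (!type %in% names(S$sets)) {
    stop("cell type not in marker set: ", type, call. = FALSE)
  }
  if (length(S$sets) == 1L) {
    stop("cannot mask the only cell type in the marker set", call. = FALSE)
  }
  marker_set(S$sets[setdiff(names(S$sets), type)],
             tissue = S$tissue, bounds = S$bounds)
}
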
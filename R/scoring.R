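#' Apply specificity weights to a z-scored matrix
#'
#' Multiplies each gene's standardized profile by its specificity weight:
#' `Z~[i, j] = Z[i, j] * theta[i]`.
#'
#' @param Z an `expr_matrix` with `layer == "zscore"`, rows restricted to
#'   the marker universe.
#' @param W a `specificity_weights` object covering all rows of `Z`.
#' @return an `expr_matrix` with `layer == "weighted_zscore"`.
#' @export
weighted_z <- function(Z, W) {
  stopifnot(inherits(Z, "expr_matrix"), inherits(W, "specificity_weights"))
  if (Z$layer != "zscore") stop("`Z` must be the zscore layer", call. = FALSE)
  g <- rownames(Z$values)
  missing <- setdiff(g, names(W$theta))
  if (length(missing)) {
    stop("no specificity weight for genes: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  v <- as_dense(Z$values) * W$theta[g]
  expression_matrix(v, layer = "weighted_zscore")
}

#' Marker enrichment scores
#'
#' For each cell type `c` and cell `j`, the enrichment score is the
#' size-normalized sum of weighted z-scores of the type's markers:
#' \deqn{E_{c,j} = \frac{1}{\sqrt{|S_c|}} \sum_{i \in S_c} \tilde Z_{i,j}.}
#' Implemented as a single matrix product of a per-type indicator/weight
#' matrix with the weighted z-score matrix. Marker genes absent from the
#' matrix are dropped from their set and the normalization uses the
#' reduced size; a warning lists the dropped genes. A cell type left with
#' no available markers gets a row of `NaN` (it can never win the argmax)
#' and a warning.
#'
#' @param Zt an `expr_matrix` with `layer == "weighted_zscore"` (or
#'   `"zscore"` when all weights are 1).
#' @param S a `marker_set`.
#' @return a `cell_annotation` object with the `scores` matrix (cell
#'   types x cells) filled in; labels are assigned separately by
#'   [assign_labels()].
#' @export
enrichment_scores <- function(Zt, S) {
  stopifnot(inherits(Zt, "expr_matrix"), inherits(S, "marker_set"))
  if (!Zt$layer %in% c("weighted_zscore", "zscore")) {
    stop("`Zt` must be a (weighted) zscore layer", call. = FALSE)
  }
  v <- as_dense(Zt$values)
  avail <- rownames(v)
  dropped <- setdiff(marker_universe(S), avail)
  if (length(dropped)) {
    warning("marker genes absent from the matrix were dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  A <- indicator_weights(S, avail)
  scores <- A %*% v
  if (any(attr(A, "n_avail") == 0)) {
    bad <- names(which(attr(A, "n_avail") == 0))
    warning("cell types with no available marker genes score NaN: ",
            paste(bad, collapse = ", "), call. = FALSE)
    scores[bad, ] <- NaN
  }
  new_annotation(scores)
}

# C x m matrix of 1/sqrt(|S_c avail|) indicators over `genes`; attribute
# n_avail records per-type available marker counts.
indicator_weights <- function(S, genes) {
  types <- names(S$sets)
  A <- matrix(0, length(types), length(genes),
              dimnames = list(types, genes))
  n_avail <- integer(length(types))
  names(n_avail) <- types
  for (c in types) {
    g <- intersect(S$sets[[c]], genes)
    n_avail[c] <- length(g)
    if (length(g)) A[c, g] <- 1 / sqrt(length(g))
  }
  attr(A, "n_avail") <- n_avail
  A
}

new_annotation <- function(scores, labels = NULL, top_score = NULL,
                           threshold = NA_real_) {
  structure(list(scores = scores, labels = labels, top_score = top_score,
                 threshold = threshold),
            class = "cell_annotation")
}

#' Assign cell type labels from enrichment scores
#'
#' Each cell is labelled with the cell type of its highest enrichment
#' score. Cells whose best score does not exceed `unknown_threshold`
#' (default 0, i.e. below-average marker expression) are labelled
#' `"unknown"`. Exact ties are broken toward the lexicographically
#' smallest cell type name, making assignment deterministic and invariant
#' to the enumeration order of cell types.
#'
#' @param E a `cell_annotation` with scores (from [enrichment_scores()]).
#' @param unknown_threshold label a cell `"unknown"` when its top score is
#'   `<=` this value.
#' @return the `cell_annotation` with `labels` and `top_score` filled in.
#' @export
assign_labels <- function(E, unknown_threshold = 0) {
  stopifnot(inherits(E, "cell_annotation"))
  sc <- E$scores[order(rownames(E$scores)), , drop = FALSE]
  sc_cmp <- sc
  sc_cmp[!is.finite(sc_cmp)] <- -Inf
  idx <- max.col(t(sc_cmp), ties.method = "first")
  top <- sc_cmp[cbind(idx, seq_len(ncol(sc_cmp)))]
  labels <- rownames(sc)[idx]
  labels[!is.finite(top) | top <= unknown_threshold] <- "unknown"
  top[!is.finite(top)] <- NaN
  names(labels) <- colnames(sc)
  E$labels <- labels
  E$top_score <- stats::setNames(top, colnames(sc))
  E$threshold <- unknown_threshold
  E
}

#' @export
print.cell_annotation <- function(x, ...) {
  cat(sprintf("<cell_annotation> %d cell types x %d cells\n",
              nrow(x$scores), ncol(x$scores)))
  if (!is.null(x$labels)) {
    tab <- sort(table(x$labels), decreasing = TRUE)
    cat("  labels:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else {
    cat("  labels: not assigned yet (see assign_labels)\n")
  }
  invisible(x)
}

#' @export
summary.cell_annotation <- function(object, ...) {
  out <- list(
    n_cells = ncol(object$scores),
    n_types = nrow(object$scores),
    label_counts = if (!is.null(object$labels)) table(object$labels),
    score_range = range(object$scores[is.finite(object$scores)])
  )
  class(out) <- "summary.cell_annotation"
  out
}

#' @export
print.summary.cell_annotation <- function(x, ...) {
  cat(sprintf("cell annotation: %d cells scored against %d cell types\n",
              x$n_cells, x$n_types))
  cat(sprintf("score range: [%.3f, %.3f]\n",
              x$score_range[1], x$score_range[2]))
  if (!is.null(x$label_counts)) print(x$label_counts)
  invisible(x)
}

#' Annotate cells with a marker gene set
#'
#' The full scoring pipeline: optional QC filtering of raw counts,
#' library-size normalization, per-gene z-scoring restricted to the
#' marker universe, specificity weighting, enrichment scoring and label
#' assignment. Input may be raw counts (`layer == "raw"`, normalized
#' internally) or an already-normalized matrix such as TPM
#' (`layer == "normalized"`, used as is).
#'
#' @param x an `expr_matrix`, raw or normalized.
#' @param S a `marker_set`.
#' @param unknown_threshold passed to [assign_labels()].
#' @param min_genes,max_umis QC thresholds applied to raw input before
#'   normalization; the defaults (`0`, `Inf`) disable QC. See
#'   [qc_filter()] for the conventional nuclear RNA-seq thresholds.
#' @param clusters optional per-cell cluster assignment (vector named by
#'   cell id, or in cell order). When supplied, scores are summed within
#'   each cluster and every cell of a cluster receives the cluster's best
#'   type; a cluster is `"unknown"` when its best summed score is below
#'   `n_cluster / 4`.
#' @param scale_factor normalization target, see [normalize_counts()].
#' @return a `cell_annotation` with scores, labels and top scores.
#' @details At least half of the marker universe must be present in the
#'   matrix for a quiet run; fewer triggers a warning, none is an error.
#' @examples
#' sim <- simulate_dataset(n_types = 3, cells_per_type = 40, n_genes = 300,
#'                         markers_per_type = 5, seed = 1)
#' ann <- annotate(sim$X, sim$markers)
#' mean(ann$labels == sim$labels[names(ann$labels)])
#' @export
annotate <- function(x, S, unknown_threshold = 0,
                     min_genes = 0, max_umis = Inf, clusters = NULL,
                     scale_factor = 1e4) {
  stopifnot(inherits(x, "expr_matrix"), inherits(S, "marker_set"))
  universe <- marker_universe(S)
  found <- intersect(universe, gene_ids(x))
  if (length(found) == 0L) {
    stop("none of the marker genes are present in the expression matrix",
         call. = FALSE)
  }
  if (length(found) < length(universe) / 2) {
    warning(sprintf("only %d of %d marker genes found in the matrix",
                    length(found), length(universe)), call. = FALSE)
  }
  if (x$layer == "raw") {
    if (min_genes > 0 || is.finite(max_umis)) {
      x <- qc_filter(x, min_genes = min_genes, max_umis = max_umis)
    }
    x <- normalize_counts(x, scale_factor = scale_factor)
  } else if (x$layer != "normalized") {
    stop("annotate expects a raw or normalized layer", call. = FALSE)
  }
  Z <- zscore_genes(x, restrict_to = found)
  W <- specificity_weights(S)
  Zt <- weighted_z(Z, W)
  E <- suppressWarnings(enrichment_scores(Zt, S))
  dropped <- setdiff(universe, found)
  if (length(dropped)) {
    warning("marker genes absent from the matrix were dropped: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  if (is.null(clusters)) {
    assign_labels(E, unknown_threshold)
  } else {
    assign_cluster_labels(E, clusters)
  }
}

# cluster-level assignment: sum scores over a cluster's cells; the
# cluster is unknown when the best summed score falls below n_cluster/4
assign_cluster_labels <- function(E, clusters) {
  cells <- colnames(E$scores)
  cl <- if (!is.null(names(clusters))) clusters[cells] else clusters
  if (length(cl) != length(cells) || anyNA(cl)) {
    stop("`clusters` must cover every scored cell", call. = FALSE)
  }
  cl <- as.character(cl)
  sc <- E$scores[order(rownames(E$scores)), , drop = FALSE]
  sc[!is.finite(sc)] <- -Inf
  labels <- character(length(cells))
  top <- numeric(length(cells))
  for (k in unique(cl)) {
    j <- which(cl == k)
    sums <- rowSums(sc[, j, drop = FALSE])
    best <- which.max(sums)  # rows sorted, so first max is lexicographic
    lab <- if (sums[best] < length(j) / 4) "unknown" else rownames(sc)[best]
    labels[j] <- lab
    top[j] <- sums[best]
  }
  E$labels <- stats::setNames(labels, cells)
  E$top_score <- stats::setNames(top, cells)
  E$threshold <- NA_real_
  E
}

# Fast internal scorer reused by CV and the optimizer: Z is a plain
# dense z-score matrix over (a superset of) the marker universe; theta is
# folded into the indicator product so no per-call weighting pass is
# needed. Returns the label vector only.
score_labels <- function(Z, S, unknown_threshold = 0, cols = NULL) {
  theta <- specificity_weights(S)$theta
  genes <- intersect(names(theta), rownames(Z))
  A <- indicator_weights(S, genes)
  n_avail <- attr(A, "n_avail")
  A <- A * rep(theta[genes], each = nrow(A))
  Zs <- if (is.null(cols)) Z[genes, , drop = FALSE] else Z[genes, cols, drop = FALSE]
  scores <- A %*% Zs
  if (any(n_avail == 0)) scores[n_avail == 0, ] <- -Inf
  ord <- order(rownames(scores))
  scores <- scores[ord, , drop = FALSE]
  idx <- max.col(t(scores), ties.method = "first")
  top <- scores[cbind(idx, seq_len(ncol(scores)))]
  labels <- rownames(scores)[idx]
  labels[!is.finite(top) | top <= unknown_threshold] <- "unknown"
  stats::setNames(labels, colnames(Zs))
}
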
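#' Expression matrix container
#'
#' A light container for a genes x cells expression matrix. Gene and cell
#' identifiers are carried as the dimnames of `values` and must be unique.
#' The `layer` tag records what the numbers mean along the pipeline:
#' `"raw"` (non-negative counts), `"normalized"` (library-size scaled,
#' log1p), `"zscore"` (per-gene standardized) or `"weighted_zscore"`
#' (z-scores multiplied by marker specificity weights).
#'
#' @param values numeric matrix or [Matrix::Matrix] with genes as rows and
#'   cells as columns; both dimnames must be set and unique.
#' @param layer one of `"raw"`, `"normalized"`, `"zscore"`,
#'   `"weighted_zscore"`.
#' @return an object of class `expr_matrix`: a list with elements `values`
#'   and `layer`.
#' @examples
#' m <- matrix(rpois(12, 2), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
#' x <- expression_matrix(m)
#' dim(x)
#' @export
expression_matrix <- function(values,
                              layer = c("raw", "normalized", "zscore",
                                        "weighted_zscore")) {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || methods::is(values, "Matrix"))) {
    stop("`values` must be a matrix or a Matrix object", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("expression matrix must have at least one gene and one cell",
         call. = FALSE)
  }
  gid <- rownames(values)
  cid <- colnames(values)
  if (is.null(gid) || is.null(cid)) {
    stop("`values` must carry gene ids as rownames and cell ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(gid)) stop("gene ids are not unique", call. = FALSE)
  if (anyDuplicated(cid)) stop("cell ids are not unique", call. = FALSE)
  if (layer == "raw" && min_value(values) < 0) {
    stop("raw layer must be non-negative", call. = FALSE)
  }
  structure(list(values = values, layer = layer), class = "expr_matrix")
}

min_value <- function(v) {
  if (methods::is(v, "sparseMatrix")) min(0, min(v@x, Inf)) else min(v)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d cells, layer = %s, %s storage\n",
              nrow(x$values), ncol(x$values), x$layer,
              if (methods::is(x$values, "sparseMatrix")) "sparse" else "dense"))
  invisible(x)
}

#' Gene and cell identifiers
#' @param x an `expr_matrix`
#' @return character vector of ids
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
cell_ids <- function(x) colnames(x$values)

#' Quality-control filter on cells
#'
#' Keeps cells with at least `min_genes` detected genes (nonzero counts)
#' and at most `max_umis` total counts. The defaults are the thresholds
#' used for nuclear RNA-seq QC (200 genes, 20,000 UMIs). Gene set and cell
#' order are preserved.
#'
#' @param x an `expr_matrix` with `layer == "raw"`.
#' @param min_genes minimum number of detected genes per cell.
#' @param max_umis maximum total counts per cell.
#' @return the filtered `expr_matrix` (raw layer).
#' @export
qc_filter <- function(x, min_genes = 200, max_umis = 20000) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "raw") stop("qc_filter expects raw counts", call. = FALSE)
  detected <- Matrix::colSums(x$values > 0)
  total <- Matrix::colSums(x$values)
  keep <- detected >= min_genes & total <= max_umis
  if (!any(keep)) {
    stop("qc_filter removed all cells (min_genes = ", min_genes,
         ", max_umis = ", max_umis, ")", call. = FALSE)
  }
  expression_matrix(x$values[, keep, drop = FALSE], layer = "raw")
}

#' Library-size normalization
#'
#' Scales each cell to a common total (`scale_factor`) and applies
#' `log(1 + x)`.
#'
#' @param x an `expr_matrix` with raw counts.
#' @param scale_factor target per-cell total before the log transform.
#' @return an `expr_matrix` with `layer == "normalized"`.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer != "raw") stop("normalize_counts expects raw counts", call. = FALSE)
  totals <- Matrix::colSums(x$values)
  if (any(totals == 0)) {
    bad <- colnames(x$values)[totals == 0]
    stop("cells with zero total counts cannot be normalized: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) sprintf(" (and %d more)", length(bad) - 5) else "",
         call. = FALSE)
  }
  f <- scale_factor / totals
  v <- x$values
  if (methods::is(v, "sparseMatrix")) {
    v <- v %*% Matrix::Diagonal(x = f)
    dimnames(v) <- dimnames(x$values)
    v <- log1p(v)
  } else {
    v <- log1p(sweep(v, 2, f, `*`))
  }
  expression_matrix(v, layer = "normalized")
}

#' Per-gene z-scoring across cells
#'
#' Standardizes each gene's expression profile across all cells:
#' `(x - mean) / sd` with the sample standard deviation (denominator
#' `n - 1`). Genes with zero variance map to an all-zero row rather than
#' NaN. Optionally restricts to a gene subset first (the marker universe),
#' which is how the scorer limits work to marker genes.
#'
#' @param x an `expr_matrix`, normally with `layer == "normalized"`.
#' @param restrict_to optional character vector of gene ids to retain;
#'   all must be present in `x`.
#' @return a dense `expr_matrix` with `layer == "zscore"`.
#' @export
zscore_genes <- function(x, restrict_to = NULL) {
  stopifnot(inherits(x, "expr_matrix"))
  if (x$layer %in% c("zscore", "weighted_zscore")) {
    stop("input is already standardized (layer = ", x$layer, ")", call. = FALSE)
  }
  v <- x$values
  if (!is.null(restrict_to)) {
    missing <- setdiff(restrict_to, rownames(v))
    if (length(missing)) {
      stop("genes not present in the matrix: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    v <- v[restrict_to, , drop = FALSE]
  }
  v <- as_dense(v)
  n <- ncol(v)
  mu <- rowMeans(v)
  centered <- v - mu
  sdv <- if (n > 1) sqrt(rowSums(centered^2) / (n - 1)) else rep(0, nrow(v))
  z <- centered / sdv
  z[sdv == 0 | !is.finite(sdv), ] <- 0
  expression_matrix(z, layer = "zscore")
}
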
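#' Stratified K-fold assignment
#'
#' Splits cells into `K` folds, stratified by true cell type so each
#' type's cells are spread across folds as evenly as possible (a type
#' with fewer cells than folds lands in that many distinct folds).
#' Deterministic given `seed`.
#'
#' @param true_labels character vector of per-cell type labels.
#' @param K number of folds (>= 2).
#' @param seed integer seed.
#' @return an object of class `fold_assignment`: list with `fold`
#'   (integers in `0:(K-1)`, one per cell, named when `true_labels` is),
#'   `K` and `seed`.
#' @export
make_folds <- function(true_labels, K = 5, seed = 1) {
  stopifnot(K >= 2)
  true_labels <- as.character(true_labels)
  if (any(table(true_labels) < 1)) stop("every type needs >= 1 cell")
  fold <- integer(length(true_labels))
  with_seed(seed, {
    for (ty in sort(unique(true_labels))) {
      idx <- which(true_labels == ty)
      perm <- if (length(idx) > 1) sample(idx) else idx
      start <- sample.int(K, 1L) - 1L
      fold[perm] <- (seq_along(perm) - 1L + start) %% K
    }
  })
  names(fold) <- names(true_labels)
  structure(list(fold = fold, K = as.integer(K), seed = seed),
            class = "fold_assignment")
}

#' Leave-one-cell-type-out accuracy on one fold
#'
#' Masks cell type `type`'s markers out of `S` (recomputing specificity
#' weights on the reduced set), annotates the held-out cells, and scores
#' the proportion of correctly assigned cells. A cell of a non-masked
#' type is correct when its predicted label equals its true type; a cell
#' of the masked type is correct when it is predicted `"unknown"` — the
#' behaviour masking is designed to produce. Set
#' `masked_rule = "always_wrong"` to instead count masked-type cells as
#' never correct (sensitivity analysis).
#'
#' Gene standardization uses all cells of `x` (means and sds are shared
#' with the training folds, as the scorer standardizes across all cells);
#' only the accuracy is restricted to the held-out fold.
#'
#' @param x an `expr_matrix` (raw or normalized).
#' @param true_labels per-cell true types, in cell order or named by cell.
#' @param S a `marker_set` containing `type`.
#' @param type the cell type to mask.
#' @param fold indices (or logical mask) of the held-out cells.
#' @param unknown_threshold passed to the scorer.
#' @param masked_rule how masked-type cells count toward accuracy.
#' @return accuracy in `[0, 1]`.
#' @export
locto_fold_accuracy <- function(x, true_labels, S, type, fold,
                                unknown_threshold = 0,
                                masked_rule = c("unknown_correct",
                                                "always_wrong")) {
  masked_rule <- match.arg(masked_rule)
  stopifnot(inherits(x, "expr_matrix"))
  if (is.logical(fold)) fold <- which(fold)
  if (length(fold) == 0L) stop("empty evaluation fold", call. = FALSE)
  Z <- cv_zscore(x, S)
  locto_accuracy_engine(Z, as.character(true_labels), S, type, fold,
                        unknown_threshold, masked_rule)
}

# full-matrix z-scores over the marker genes present in x
cv_zscore <- function(x, S) {
  if (x$layer == "raw") x <- normalize_counts(x)
  genes <- intersect(marker_universe(S), gene_ids(x))
  if (length(genes) == 0L) {
    stop("no marker genes present in the expression matrix", call. = FALSE)
  }
  as_dense(zscore_genes(x, restrict_to = genes)$values)
}

locto_accuracy_engine <- function(Z, true_labels, S, type, fold,
                                  unknown_threshold, masked_rule) {
  if (length(fold) == 0L) stop("empty evaluation fold", call. = FALSE)
  Sm <- mask_cell_type(S, type)
  pred <- score_labels(Z, Sm, unknown_threshold, cols = fold)
  truth <- true_labels[fold]
  correct <- ifelse(truth == type,
                    if (masked_rule == "unknown_correct") pred == "unknown"
                    else FALSE,
                    pred == truth)
  mean(correct)
}

#' Cross-validation report
#'
#' Container for per-(cell type, fold) leave-one-cell-type-out
#' accuracies. The objective is their grand mean,
#' `f(S) = (1 / (C K)) sum_c sum_k f_{c,k}(S)`.
#'
#' @param per_type_fold numeric `C x K` matrix of accuracies in `[0, 1]`,
#'   rows named by cell type.
#' @return an object of class `cv_report` with elements `per_type_fold`,
#'   `objective`, `C` and `K`.
#' @export
cv_report <- function(per_type_fold) {
  stopifnot(is.matrix(per_type_fold),
            all(per_type_fold >= 0 & per_type_fold <= 1))
  structure(list(per_type_fold = per_type_fold,
                 objective = mean(per_type_fold),
                 C = nrow(per_type_fold), K = ncol(per_type_fold)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> C = %d cell types x K = %d folds, f(S) = %.4f\n",
              x$C, x$K, x$objective))
  means <- rowMeans(x$per_type_fold)
  for (nm in utils::head(names(means), 10)) {
    cat(sprintf("  %-20s %.4f\n", nm, means[nm]))
  }
  if (length(means) > 10) cat("  ...\n")
  invisible(x)
}

#' LOCTO x K-fold cross-validated objective
#'
#' Scores a candidate marker set: for every cell type `c` the type's
#' markers are masked, every fold's held-out cells are annotated with the
#' masked set, and the accuracy `f_{c,k}` is recorded
#' (see [locto_fold_accuracy()]). The objective is the grand mean over
#' all `C x K` cells of the accuracy matrix. Deterministic given `seed`
#' (which drives only the fold split).
#'
#' @inheritParams locto_fold_accuracy
#' @param K number of folds.
#' @param seed fold-split seed.
#' @param folds optional precomputed `fold_assignment` (overrides
#'   `K`/`seed`).
#' @return a `cv_report`.
#' @export
cv_objective <- function(x, true_labels, S, K = 5, seed = 1,
                         unknown_threshold = 0,
                         masked_rule = c("unknown_correct", "always_wrong"),
                         folds = NULL) {
  masked_rule <- match.arg(masked_rule)
  true_labels <- as.character(true_labels)
  if (length(unique(true_labels)) < 2L) {
    stop("true labels must cover at least two cell types", call. = FALSE)
  }
  Z <- cv_zscore(x, S)
  if (is.null(folds)) folds <- make_folds(true_labels, K = K, seed = seed)
  cv_objective_engine(Z, true_labels, S, folds, unknown_threshold, masked_rule)
}

cv_objective_engine <- function(Z, true_labels, S, folds,
                                unknown_threshold = 0,
                                masked_rule = "unknown_correct") {
  types <- names(S$sets)
  K <- folds$K
  acc <- matrix(NA_real_, length(types), K,
                dimnames = list(types, paste0("fold", seq_len(K) - 1L)))
  fold_idx <- split(seq_along(folds$fold), folds$fold)
  for (ty in types) {
    for (k in seq_len(K)) {
      idx <- fold_idx[[as.character(k - 1L)]]
      acc[ty, k] <- locto_accuracy_engine(Z, true_labels, S, ty, idx,
                                          unknown_threshold, masked_rule)
    }
  }
  cv_report(acc)
}

#' Write a cross-validation report to disk
#'
#' Long-format TSV (cell_type, fold, accuracy) plus a JSON summary with
#' the objective.
#'
#' @param report a `cv_report`.
#' @param path TSV output path; the JSON summary goes to
#'   `sub("\\\\.tsv$", ".json", path)` unless `json_path` is given.
#' @param json_path optional explicit JSON path.
#' @export
write_cv_report <- function(report, path, json_path = NULL) {
  stopifnot(inherits(report, "cv_report"))
  long <- data.frame(
    cell_type = rep(rownames(report$per_type_fold), report$K),
    fold = rep(seq_len(report$K) - 1L, each = report$C),
    accuracy = as.vector(report$per_type_fold)
  )
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json_path <- json_path %||% sub("\\.tsv$", ".json", path)
  jsonlite::write_json(
    list(objective = report$objective, C = report$C, K = report$K),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
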
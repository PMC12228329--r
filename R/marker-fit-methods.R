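# S3 methods for the fitted marker-set model

#' @export
print.marker_fit <- function(x, ...) {
  cat("Marker-set optimization fit\n")
  cat(sprintf("  method: %s, budget: %d evaluations, seed: %d\n",
              x$method, x$budget_used, x$seed))
  cat(sprintf("  best LOCTO x %d-fold objective f(S*) = %.4f\n",
              x$K, x$best_objective))
  cat(sprintf("  %d cell types, %d genes in optimized universe\n",
              length(x$best_set$sets), length(marker_universe(x$best_set))))
  invisible(x)
}

#' @export
summary.marker_fit <- function(object, ...) {
  sizes <- lengths(object$best_set$sets)
  out <- list(
    method = object$method,
    best_objective = object$best_objective,
    initial_objective = object$trace$objective[1],
    evaluations = nrow(object$trace),
    set_sizes = sizes,
    improved_at = object$trace$iteration[
      c(TRUE, diff(object$trace$f_best) > 0)]
  )
  class(out) <- "summary.marker_fit"
  out
}

#' @export
print.summary.marker_fit <- function(x, ...) {
  cat(sprintf("marker-set fit (%s): f(S) %.4f -> %.4f over %d evaluations\n",
              x$method, x$initial_objective, x$best_objective,
              x$evaluations))
  cat("per-type marker counts:\n")
  print(x$set_sizes)
  cat("improvements at iterations:",
      paste(utils::head(x$improved_at, 15), collapse = ", "), "\n")
  invisible(x)
}

#' Extract the optimized marker sets
#'
#' The "coefficients" of a marker-set fit are the per-type marker gene
#' lists of the best set found.
#'
#' @param object a `marker_fit`.
#' @param ... unused.
#' @return named list of character vectors (cell type -> genes).
#' @export
coef.marker_fit <- function(object, ...) {
  object$best_set$sets
}

#' Annotate new cells with the optimized marker set
#'
#' @param object a `marker_fit`.
#' @param newdata an `expr_matrix` of query cells.
#' @param ... passed to [annotate()].
#' @return a `cell_annotation`.
#' @export
predict.marker_fit <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expr_matrix"))
  annotate(newdata, object$best_set, ...)
}

#' Optimization trace plot
#'
#' Observed objective per iteration with the running best overlaid.
#'
#' @param x a `marker_fit`.
#' @param ... passed to [plot()].
#' @export
plot.marker_fit <- function(x, ...) {
  tr <- x$trace
  plot(tr$iteration, tr$objective, pch = 16, cex = 0.5, col = "grey50",
       xlab = "iteration", ylab = "LOCTO CV objective f(S)", ...)
  graphics::lines(tr$iteration, tr$f_best, col = "firebrick", lwd = 2)
  graphics::legend("bottomright", c("evaluated", "running best"),
                   col = c("grey50", "firebrick"), pch = c(16, NA),
                   lty = c(NA, 1), bty = "n")
  invisible(x)
}

#' Serialize an optimization result
#'
#' Writes the best set, objective and settings as JSON and the trace as
#' TSV next to it.
#'
#' @param fit a `marker_fit`.
#' @param path JSON output path; trace goes to
#'   `sub("\\\\.json$", "_trace.tsv", path)`.
#' @export
write_marker_fit <- function(fit, path) {
  stopifnot(inherits(fit, "marker_fit"))
  jsonlite::write_json(
    list(best_objective = fit$best_objective,
         method = fit$method, seed = fit$seed,
         bounds = fit$bounds, budget = fit$budget_used,
         tissue = fit$best_set$tissue,
         cell_types = fit$best_set$sets),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.table(fit$trace, sub("\\.json$", "_trace.tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
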
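#' Simulate a single-cell count matrix with planted cell types
#'
#' Generates a genes x cells negative-binomial count matrix with discrete
#' cell types and planted marker genes. Per-gene baseline means are
#' lognormal around `base_mean`; each type's planted markers have their
#' mean multiplied by `2^marker_log2fc` in that type's cells; per-cell
#' size factors are lognormal with sd `libsize_sigma`; counts are drawn
#' negative-binomial with mean `mu` and variance
#' `mu + mu^2 / nb_dispersion` (i.e. `size = nb_dispersion`).
#'
#' Defaults describe a small but clearly structured dataset: 5 types,
#' 300 cells/type, 2,000 genes, 8 disjoint markers per type at log2
#' fold-change 2. Planted markers are sampled without replacement from
#' the detectably expressed genes (baseline mean at or above the median),
#' since a fold change on a near-silent gene is invisible at single-cell
#' depth. They are disjoint across types unless `overlap_markers = TRUE`,
#' in which case
#' every type draws from a shared restricted pool so some markers are
#' shared (exercising specificity weights below 1).
#'
#' @param n_types number of cell types.
#' @param cells_per_type cells per type.
#' @param n_genes total genes.
#' @param markers_per_type planted markers per type.
#' @param marker_log2fc marker effect size in log2 units.
#' @param nb_dispersion negative-binomial size parameter (larger = less
#'   overdispersed).
#' @param base_mean median baseline expected counts per gene per cell.
#' @param libsize_sigma lognormal sd of per-cell size factors (0 = none).
#' @param overlap_markers allow shared markers across types.
#' @param seed integer seed; identical seeds give identical datasets.
#' @return an object of class `sim_data`: list with `X` (raw-count
#'   `expr_matrix`), `labels` (named character vector of true types) and
#'   `markers` (the planted `marker_set`).
#' @examples
#' sim <- simulate_dataset(n_types = 3, cells_per_type = 50,
#'                         n_genes = 400, seed = 7)
#' table(sim$labels)
#' @export
simulate_dataset <- function(n_types = 5, cells_per_type = 300,
                             n_genes = 2000, markers_per_type = 8,
                             marker_log2fc = 2, nb_dispersion = 2,
                             base_mean = 0.5, libsize_sigma = 0.3,
                             overlap_markers = FALSE, seed = 1) {
  if (n_types < 1) stop("invalid `n_types`", call. = FALSE)
  if (cells_per_type < 1) stop("invalid `cells_per_type`", call. = FALSE)
  if (n_genes < 1) stop("invalid `n_genes`", call. = FALSE)
  if (markers_per_type < 1) stop("invalid `markers_per_type`", call. = FALSE)
  if (markers_per_type * n_types > n_genes) {
    stop("`markers_per_type` * `n_types` exceeds `n_genes`", call. = FALSE)
  }
  if (nb_dispersion <= 0) stop("invalid `nb_dispersion`", call. = FALSE)
  if (base_mean <= 0) stop("invalid `base_mean`", call. = FALSE)
  if (libsize_sigma < 0) stop("invalid `libsize_sigma`", call. = FALSE)

  genes <- sprintf("gene%04d", seq_len(n_genes))
  types <- sprintf("type%02d", seq_len(n_types))
  n_cells <- n_types * cells_per_type
  cells <- sprintf("cell%05d", seq_len(n_cells))
  labels <- stats::setNames(rep(types, each = cells_per_type), cells)

  with_seed(seed, {
    lambda <- stats::rlnorm(n_genes, meanlog = log(base_mean), sdlog = 1)
    names(lambda) <- genes
    # markers must be detectably expressed: a fold change on a near-silent
    # gene carries no signal, so plant only on genes at or above the
    # median baseline (falling back to the top expressed genes when the
    # gene count is tiny)
    n_marked <- n_types * markers_per_type
    expressed <- genes[lambda >= stats::median(lambda)]
    if (length(expressed) < n_marked) {
      expressed <- genes[order(lambda, decreasing = TRUE)][seq_len(n_marked)]
    }
    planted <- if (overlap_markers) {
      shared_pool <- sample(expressed,
                            max(markers_per_type,
                                ceiling(n_marked * 0.6)))
      lapply(types, function(t) sample(shared_pool, markers_per_type))
    } else {
      picked <- sample(expressed, n_marked)
      split(picked, rep(seq_len(n_types), each = markers_per_type))
    }
    names(planted) <- types
    sf <- if (libsize_sigma > 0) {
      stats::rlnorm(n_cells, meanlog = 0, sdlog = libsize_sigma)
    } else {
      rep(1, n_cells)
    }
    counts <- matrix(0L, n_genes, n_cells, dimnames = list(genes, cells))
    for (ti in seq_len(n_types)) {
      j <- which(labels == types[ti])
      mu_g <- lambda
      mu_g[planted[[ti]]] <- mu_g[planted[[ti]]] * 2^marker_log2fc
      mu <- outer(mu_g, sf[j])
      counts[, j] <- stats::rnbinom(length(mu), mu = mu,
                                    size = nb_dispersion)
    }
    structure(
      list(X = expression_matrix(counts, layer = "raw"),
           labels = labels,
           markers = marker_set(planted, tissue = "synthetic",
                                bounds = c(1L, 30L))),
      class = "sim_data")
  })
}

#' @export
print.sim_data <- function(x, ...) {
  cat(sprintf("<sim_data> %d genes x %d cells, %d types, %d markers/type\n",
              nrow(x$X$values), ncol(x$X$values),
              length(x$markers$sets),
              length(x$markers$sets[[1]])))
  invisible(x)
}

#' Precision and recall of recovered marker sets
#'
#' Compares a found marker set against the planted truth, per cell type
#' and macro-averaged.
#'
#' @param found,truth `marker_set` objects over the same cell type names.
#' @return list with a per-type data.frame (`per_type`: cell_type,
#'   precision, recall) and macro averages `precision` and `recall`.
#' @export
planted_recovery <- function(found, truth) {
  stopifnot(inherits(found, "marker_set"), inherits(truth, "marker_set"))
  if (!setequal(names(found$sets), names(truth$sets))) {
    stop("marker sets are over different cell type names", call. = FALSE)
  }
  types <- names(truth$sets)
  per <- data.frame(
    cell_type = types,
    precision = vapply(types, function(ty) {
      length(intersect(found$sets[[ty]], truth$sets[[ty]])) /
        length(found$sets[[ty]])
    }, 0),
    recall = vapply(types, function(ty) {
      length(intersect(found$sets[[ty]], truth$sets[[ty]])) /
        length(truth$sets[[ty]])
    }, 0),
    row.names = NULL
  )
  list(per_type = per,
       precision = mean(per$precision),
       recall = mean(per$recall))
}
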
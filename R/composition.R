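#' Permutation test for shifts in cell type composition
#'
#' Tests, per cell type, whether the type's proportion differs between
#' two conditions. The statistic is
#' `proportion(cond_b) - proportion(cond_a)`; its null distribution is
#' built by permuting condition labels over cells (default) or over
#' samples. With `alternative = "less"` (proportions in `cond_b` lower
#' than in `cond_a`, the convention for injury-versus-sham comparisons)
#' the Monte-Carlo p-value is `(1 + #{perm <= observed}) / (n_perm + 1)`.
#' When the number of distinct label arrangements is at most
#' `exhaustive_limit` the test enumerates all of them and returns the
#' exact fraction instead.
#'
#' Benjamini-Hochberg adjusted p-values across cell types are reported
#' alongside the raw ones.
#'
#' @param table data.frame with columns `sample`, `condition`,
#'   `cell_type`, `count` (cells of that type in that sample); each
#'   sample must belong to exactly one condition.
#' @param cond_a,cond_b condition names to compare (the alternative is
#'   about `cond_b` relative to `cond_a`).
#' @param n_perm Monte-Carlo permutations (ignored in exhaustive mode).
#' @param alternative `"less"`, `"greater"` or `"two.sided"`.
#' @param seed seed for the Monte-Carlo draw.
#' @param unit permute condition labels over `"cell"`s (default) or over
#'   `"sample"`s. At two samples per condition the sample-level test has
#'   almost no resolution; it exists for sensitivity analysis.
#' @param exhaustive_limit enumerate exactly when the number of
#'   arrangements is at most this (and `unit = "cell"` arrangements fit
#'   in memory); set to 0 to force Monte-Carlo.
#' @return data.frame of class `composition_test` with columns
#'   `cell_type`, `statistic`, `p_value`, `p_adj`; attributes `mode`
#'   (`"exhaustive"` or `"monte-carlo"`), `n_perm`, `alternative`.
#' @export
composition_test <- function(table, cond_a, cond_b, n_perm = 1000,
                             alternative = c("less", "greater",
                                             "two.sided"),
                             seed = NULL, unit = c("cell", "sample"),
                             exhaustive_limit = 1e5) {
  alternative <- match.arg(alternative)
  unit <- match.arg(unit)
  req <- c("sample", "condition", "cell_type", "count")
  if (!all(req %in% names(table))) {
    stop("`table` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (any(table$count < 0)) stop("negative counts", call. = FALSE)
  cond_of <- tapply(as.character(table$condition), table$sample,
                    function(v) unique(v))
  if (any(lengths(cond_of) != 1)) {
    stop("each sample must belong to exactly one condition", call. = FALSE)
  }
  tab <- table[table$condition %in% c(cond_a, cond_b), , drop = FALSE]
  types <- sort(unique(as.character(table$cell_type)))
  tot_a <- sum(tab$count[tab$condition == cond_a])
  tot_b <- sum(tab$count[tab$condition == cond_b])
  if (tot_a == 0 || tot_b == 0) {
    stop("a condition has zero cells", call. = FALSE)
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1", call. = FALSE)

  if (unit == "cell") {
    res <- composition_test_cells(tab, cond_a, cond_b, types, n_perm,
                                  alternative, seed, exhaustive_limit)
  } else {
    res <- composition_test_samples(tab, cond_a, cond_b, types, n_perm,
                                    alternative, seed, exhaustive_limit)
  }
  res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
  class(res) <- c("composition_test", "data.frame")
  res
}

# observed and permuted statistics from per-type membership of pooled
# cells; B is cells x n_perm logical/numeric membership in cond_b
composition_stats <- function(type_of_cell, types, b_member, n_b, n_a) {
  M <- vapply(types, function(ty) as.numeric(type_of_cell == ty),
              numeric(length(type_of_cell)))
  counts_b <- crossprod(M, b_member)          # types x n_perm
  tot_type <- colSums(M)
  counts_b / n_b - (tot_type - counts_b) / n_a
}

composition_test_cells <- function(tab, cond_a, cond_b, types, n_perm,
                                   alternative, seed, exhaustive_limit) {
  type_of_cell <- rep(as.character(tab$cell_type), tab$count)
  is_b <- rep(tab$condition == cond_b, tab$count)
  n <- length(type_of_cell)
  n_b <- sum(is_b)
  n_a <- n - n_b
  obs <- drop(composition_stats(type_of_cell, types,
                                matrix(as.numeric(is_b), ncol = 1),
                                n_b, n_a))
  n_arr <- choose(n, n_b)
  if (n_arr <= exhaustive_limit) {
    combs <- utils::combn(n, n_b)
    nc <- ncol(combs)
    perm <- matrix(NA_real_, length(types), nc)
    for (start in seq(1, nc, by = 5000)) {   # chunked to bound memory
      ix <- start:min(start + 4999, nc)
      B <- matrix(0, n, length(ix))
      B[cbind(as.vector(combs[, ix, drop = FALSE]),
              rep(seq_along(ix), each = n_b))] <- 1
      perm[, ix] <- composition_stats(type_of_cell, types, B, n_b, n_a)
    }
    p <- perm_pvalue(perm, obs, alternative, exact = TRUE)
    mode <- "exhaustive"
    n_used <- nc
  } else {
    B <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        m <- numeric(n)
        m[sample.int(n, n_b)] <- 1
        m
      }, numeric(n))
    })
    perm <- composition_stats(type_of_cell, types, B, n_b, n_a)
    p <- perm_pvalue(perm, obs, alternative, exact = FALSE)
    mode <- "monte-carlo"
    n_used <- n_perm
  }
  structure(data.frame(cell_type = types, statistic = obs, p_value = p,
                       row.names = NULL),
            mode = mode, n_perm = n_used, alternative = alternative)
}

composition_test_samples <- function(tab, cond_a, cond_b, types, n_perm,
                                     alternative, seed, exhaustive_limit) {
  samples <- unique(as.character(tab$sample))
  cond_of <- vapply(samples, function(s) {
    as.character(tab$condition[tab$sample == s][1])
  }, "")
  counts <- vapply(types, function(ty) {
    vapply(samples, function(s) {
      sum(tab$count[tab$sample == s & tab$cell_type == ty])
    }, 0)
  }, numeric(length(samples)))
  counts <- matrix(counts, nrow = length(samples),
                   dimnames = list(samples, types))
  n_sb <- sum(cond_of == cond_b)
  stat_for <- function(b_samples) {
    cb <- colSums(counts[b_samples, , drop = FALSE])
    ca <- colSums(counts[setdiff(samples, b_samples), , drop = FALSE])
    cb / sum(cb) - ca / sum(ca)
  }
  obs <- stat_for(samples[cond_of == cond_b])
  n_arr <- choose(length(samples), n_sb)
  if (n_arr <= exhaustive_limit) {
    combs <- utils::combn(length(samples), n_sb)
    perm <- apply(combs, 2, function(ix) stat_for(samples[ix]))
    p <- perm_pvalue(perm, obs, alternative, exact = TRUE)
    mode <- "exhaustive"
    n_used <- ncol(combs)
  } else {
    perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        stat_for(sample(samples, n_sb))
      }, numeric(length(types)))
    })
    p <- perm_pvalue(perm, obs, alternative, exact = FALSE)
    mode <- "monte-carlo"
    n_used <- n_perm
  }
  structure(data.frame(cell_type = types, statistic = obs, p_value = p,
                       row.names = NULL),
            mode = mode, n_perm = n_used, alternative = alternative)
}

# perm: types x n_perm matrix of permuted statistics
perm_pvalue <- function(perm, obs, alternative, exact) {
  perm <- matrix(perm, nrow = length(obs))
  tol <- 1e-12
  hits <- switch(alternative,
    less = rowSums(perm <= obs + tol),
    greater = rowSums(perm >= obs - tol),
    two.sided = rowSums(abs(perm) >= abs(obs) - tol)
  )
  if (exact) hits / ncol(perm) else (1 + hits) / (ncol(perm) + 1)
}

#' @export
print.composition_test <- function(x, ...) {
  cat(sprintf("composition permutation test (%s, alternative = %s, %s = %d)\n",
              attr(x, "mode"), attr(x, "alternative"),
              if (attr(x, "mode") == "exhaustive") "arrangements"
              else "permutations",
              attr(x, "n_perm")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
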
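# Bayesian optimization of marker gene sets: EM-driven candidate
# proposals scored by Expected Improvement under the set-kernel GP, with
# the LOCTO x K-fold objective as ground truth.

#' Propose candidate marker sets by an EM step
#'
#' E-step: cells are assigned types with the current marker set. M-step:
#' for every cell type, candidate genes are ranked by a specificity
#' statistic on the induced assignment — the gene's mean z-score within
#' the cells assigned to the type minus its largest mean z-score within
#' any other type's cells. Candidates are then seeded mutations of the
#' current set: mostly swaps of the lowest-ranked current marker for a
#' top-ranked non-member, with occasional additions and removals, always
#' within the size bounds. A cell type that received no cells keeps its
#' markers unchanged (with a warning).
#'
#' @param x an `expr_matrix` (raw or normalized).
#' @param S_current the current `marker_set`.
#' @param n_candidates number of mutated sets to propose.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @param pool candidate gene pool (default: all genes of `x`).
#' @param unknown_threshold passed to the scorer in the E-step.
#' @param top_m sample replacement genes among the `top_m` best-ranked
#'   non-members (geometric weights), for proposal diversity.
#' @return list of `marker_set` objects (empty when `n_candidates = 0`).
#' @export
em_propose <- function(x, S_current, n_candidates, seed = NULL,
                       pool = NULL, unknown_threshold = 0, top_m = 5L) {
  stopifnot(inherits(x, "expr_matrix"), inherits(S_current, "marker_set"),
            n_candidates >= 0)
  if (n_candidates == 0) return(list())
  pool <- pool %||% gene_ids(x)
  if (x$layer == "raw") x <- normalize_counts(x)
  genes <- intersect(unique(c(pool, marker_universe(S_current))), gene_ids(x))
  Z <- as_dense(zscore_genes(x, restrict_to = genes)$values)
  with_seed(seed,
            em_propose_engine(Z, S_current, n_candidates, pool,
                              S_current$bounds, unknown_threshold, top_m))
}

em_propose_engine <- function(Z, S_current, n_candidates, pool, bounds,
                              unknown_threshold = 0, top_m = 5L) {
  types <- names(S_current$sets)
  labels <- score_labels(Z, S_current, unknown_threshold)
  ms <- mstep_statistic(Z, labels, types)
  live <- types[ms$counts > 0]
  if (length(live) < length(types)) {
    warning("cell types with no assigned cells keep their markers: ",
            paste(setdiff(types, live), collapse = ", "), call. = FALSE)
  }
  if (length(live) == 0L) return(list())
  out <- vector("list", n_candidates)
  for (i in seq_len(n_candidates)) {
    out[[i]] <- mutate_set(S_current, ms$stat, live, pool, bounds, top_m)
  }
  out
}

# per-gene, per-type specificity statistic on an induced assignment:
# mean z within the type's cells minus the max mean z in any other type
mstep_statistic <- function(Z, labels, types) {
  counts <- vapply(types, function(ty) sum(labels == ty), 0L)
  ind <- matrix(0, length(labels), length(types),
                dimnames = list(NULL, types))
  for (ty in types[counts > 0]) {
    ind[labels == ty, ty] <- 1 / counts[ty]
  }
  G <- Z %*% ind                      # genes x types mean z-scores
  G[, counts == 0] <- NA_real_
  stat <- G
  for (ci in seq_along(types)) {
    others <- G[, -ci, drop = FALSE]
    mx <- if (ncol(others)) do.call(pmax, c(as.data.frame(others), na.rm = TRUE))
          else rep(0, nrow(G))
    mx[!is.finite(mx)] <- 0
    stat[, ci] <- G[, ci] - mx
  }
  list(stat = stat, counts = counts)
}

mutate_set <- function(S, stat, live, pool, bounds, top_m) {
  sets <- S$sets
  ty <- if (length(live) == 1L) live else sample(live, 1L)
  cur <- sets[[ty]]
  nonmembers <- setdiff(pool, cur)
  moves <- c("swap", "add", "remove", "rebuild")
  w <- c(0.35, 0.15, 0.25, 0.25)
  if (length(cur) >= bounds[2] || !length(nonmembers)) w[2] <- 0
  if (length(cur) <= bounds[1]) w[3] <- 0
  if (!length(nonmembers)) w[1] <- 0
  if (all(w == 0)) return(S)
  move <- sample(moves, 1L, prob = w)
  s_ty <- stat[, ty]
  rank_by_stat <- function(cands, decreasing) {
    sc <- s_ty[match(cands, rownames(stat))]
    sc[is.na(sc)] <- -Inf
    cands[order(sc, decreasing = decreasing)]
  }
  pick_best <- function(cands, r) {
    ord <- rank_by_stat(cands, decreasing = TRUE)
    m <- min(top_m + r - 1L, length(ord))
    ord[sample.int(m, r, prob = 2^-(seq_len(m)))]
  }
  worst <- function(cands, r) rank_by_stat(cands, decreasing = FALSE)[seq_len(r)]
  # multi-gene moves: swapping or dropping several of the lowest-ranked
  # markers at once lets one EM step rebuild most of a type's list
  r_geom <- function(rmax) {
    if (rmax <= 1L) return(1L)
    sample.int(rmax, 1L, prob = 2^-(seq_len(rmax)))
  }
  sets[[ty]] <- switch(
    move,
    swap = {
      r <- r_geom(min(length(cur), length(nonmembers), 4L))
      c(setdiff(cur, worst(cur, r)), pick_best(nonmembers, r))
    },
    add = {
      r <- r_geom(min(bounds[2] - length(cur), length(nonmembers), 3L))
      c(cur, pick_best(nonmembers, r))
    },
    remove = {
      r <- r_geom(min(length(cur) - bounds[1], 3L))
      setdiff(cur, worst(cur, r))
    },
    rebuild = {
      # maximizing M-step: keep the genes whose specificity statistic is
      # within a (jittered) fraction of the type's best, i.e. re-select
      # the list wholesale instead of editing it gene by gene
      s_pool <- s_ty[match(pool, rownames(stat))]
      names(s_pool) <- pool
      s_pool <- s_pool[is.finite(s_pool)]
      frac <- stats::runif(1, 0.3, 0.7)
      keep <- names(s_pool)[s_pool >= frac * max(s_pool)]
      if (length(keep) < bounds[1]) {
        keep <- names(sort(s_pool, decreasing = TRUE))[seq_len(bounds[1])]
      }
      if (length(keep) > bounds[2]) {
        keep <- names(sort(s_pool[keep],
                           decreasing = TRUE))[seq_len(bounds[2])]
      }
      keep
    }
  )
  marker_set(sets, tissue = S$tissue, bounds = S$bounds)
}

# per-type integer signatures for fast Jaccard during optimization
set_signature <- function(S, pool_index) {
  lapply(S$sets, function(g) {
    v <- pool_index[g]
    v[!is.na(v)]
  })
}

jaccard_sig <- function(a, b) {
  j <- vapply(seq_along(a), function(i) {
    x <- a[[i]]; y <- b[[i]]
    inter <- sum(match(x, y, 0L) > 0L)
    inter / (length(x) + length(y) - inter)
  }, 0)
  mean(j)
}

#' Optimize a marker gene set by Bayesian optimization
#'
#' Fits the marker-set model: searches for the marker set `S*` that
#' maximizes the leave-one-cell-type-out cross-validated annotation
#' accuracy `f(S)` (see [cv_objective()]). A Gaussian-process surrogate
#' over the set-similarity kernel models `f`; at each iteration an EM
#' step proposes a batch of mutated candidate sets, the candidate with
#' the highest Expected Improvement is evaluated with the true objective,
#' and the surrogate is updated. `method = "random"` replaces the whole
#' proposal machinery with uniform random sets at the same evaluation
#' budget (the natural baseline).
#'
#' The initial set takes, for every cell type, the top `k_max / 2` pool
#' genes ranked by the M-step specificity statistic computed on the true
#' labels.
#'
#' @param x an `expr_matrix` (raw counts or normalized).
#' @param true_labels per-cell type labels (in cell order, or named by
#'   cell id).
#' @param pool candidate gene pool (default: all genes of `x`); must
#'   contain at least `C * k_min` genes.
#' @param bounds per-type size bounds `(k_min, k_max)`, default `c(1, 30)`.
#' @param budget number of objective evaluations after the initial one.
#' @param seed single seed driving all randomness (folds, proposals);
#'   identical seeds give identical traces.
#' @param K folds for the CV objective.
#' @param batch EM candidates proposed per iteration.
#' @param gamma,noise_var GP kernel hyperparameters, see [gp_fit()].
#' @param unknown_threshold scorer threshold, see [assign_labels()].
#' @param method `"bo"` (default) or `"random"` baseline.
#' @param init optional starting `marker_set` (overrides the data-driven
#'   initialization).
#' @param verbose print progress every 25 iterations.
#' @return an object of class `marker_fit` with elements `best_set`,
#'   `best_objective`, `trace` (data.frame: iteration, objective,
#'   f_best), `history`, `seed`, `method`, `budget_used`.
#' @seealso [predict.marker_fit()], [plot.marker_fit()]
#' @export
optimize_markers <- function(x, true_labels, pool = NULL,
                             bounds = c(1L, 30L), budget = 200, seed = 1,
                             K = 5, batch = 32, gamma = 1,
                             noise_var = 1e-4, unknown_threshold = 0,
                             method = c("bo", "random"), init = NULL,
                             verbose = FALSE) {
  method <- match.arg(method)
  stopifnot(inherits(x, "expr_matrix"), budget >= 0)
  true_labels <- as.character(true_labels)
  stopifnot(length(true_labels) == ncol(x$values))
  types <- sort(unique(true_labels))
  C <- length(types)
  bounds <- as.integer(bounds)
  pool <- pool %||% gene_ids(x)
  if (!all(pool %in% gene_ids(x))) {
    stop("`pool` contains genes absent from the matrix", call. = FALSE)
  }
  if (length(pool) < C * bounds[1]) {
    stop("gene pool smaller than C * k_min", call. = FALSE)
  }
  if (x$layer == "raw") x <- normalize_counts(x)
  Z <- as_dense(zscore_genes(x, restrict_to = pool)$values)
  pool_index <- stats::setNames(seq_along(pool), pool)

  with_seed(seed, {
    folds <- make_folds(true_labels, K = K,
                        seed = sample.int(.Machine$integer.max, 1L))
    evaluate <- function(S) {
      cv_objective_engine(Z, true_labels, S, folds,
                          unknown_threshold)$objective
    }
    random_set <- function() {
      sets <- lapply(types, function(ty) {
        k <- if (bounds[1] == bounds[2]) bounds[1]
             else sample(seq(bounds[1], bounds[2]), 1L)
        sample(pool, k)
      })
      names(sets) <- types
      marker_set(sets, tissue = "optimized", bounds = bounds)
    }
    if (is.null(init)) {
      init <- if (method == "random") random_set()
              else init_from_statistic(Z, true_labels, types, pool, bounds)
    }
    f0 <- evaluate(init)
    history <- list(list(set = init, objective = f0))
    sigs <- list(set_signature(init, pool_index))
    Kmat <- matrix(1, 1, 1)
    best_set <- init
    f_best <- f0
    trace <- data.frame(iteration = 0L, objective = f0, f_best = f0)
    for (t in seq_len(budget)) {
      if (method == "random") {
        cand <- random_set()
      } else {
        cands <- suppressWarnings(
          em_propose_engine(Z, best_set, batch, pool, bounds,
                            unknown_threshold))
        if (!length(cands)) cands <- list(random_set())
        if (length(history) >= 2) {
          fit <- gp_solve(Kmat, vapply(history, `[[`, 0, "objective"),
                          noise_var)
          csigs <- lapply(cands, set_signature, pool_index = pool_index)
          kx <- vapply(csigs, function(cs) {
            vapply(sigs, function(s) {
              exp(-gamma * (1 - jaccard_sig(s, cs)))
            }, 0)
          }, numeric(length(sigs)))
          kx <- matrix(kx, nrow = length(sigs))
          ei <- gp_ei(fit, kx, f_best)
          cand <- cands[[which.max(ei)]]
        } else {
          cand <- cands[[1]]
        }
      }
      fv <- evaluate(cand)
      csig <- set_signature(cand, pool_index)
      kvec <- vapply(sigs, function(s) {
        exp(-gamma * (1 - jaccard_sig(s, csig)))
      }, 0)
      n <- nrow(Kmat)
      Kmat <- rbind(cbind(Kmat, kvec), c(kvec, 1))
      sigs[[n + 1]] <- csig
      history[[n + 1]] <- list(set = cand, objective = fv)
      if (fv > f_best) {
        f_best <- fv
        best_set <- cand
      }
      trace <- rbind(trace,
                     data.frame(iteration = t, objective = fv,
                                f_best = f_best))
      if (verbose && t %% 25 == 0) {
        message(sprintf("iteration %d: f = %.4f, f_best = %.4f",
                        t, fv, f_best))
      }
    }
    structure(list(best_set = best_set, best_objective = f_best,
                   trace = trace, history = history,
                   budget_used = budget, seed = seed, method = method,
                   bounds = bounds, K = K,
                   settings = list(batch = batch, gamma = gamma,
                                   noise_var = noise_var,
                                   unknown_threshold = unknown_threshold),
                   call = match.call()),
              class = "marker_fit")
  })
}

init_from_statistic <- function(Z, true_labels, types, pool, bounds) {
  ms <- mstep_statistic(Z, true_labels, types)
  k0 <- max(bounds[1], min(bounds[2], bounds[2] %/% 2L))
  pool_rows <- intersect(pool, rownames(ms$stat))
  sets <- lapply(types, function(ty) {
    s <- ms$stat[pool_rows, ty]
    pool_rows[order(s, decreasing = TRUE)][seq_len(min(k0, length(pool_rows)))]
  })
  names(sets) <- types
  marker_set(sets, tissue = "optimized", bounds = bounds)
}

# plain GP solve on a precomputed Gram matrix (optimizer fast path);
# mirrors gp_fit but reuses the incrementally grown Gram
gp_solve <- function(Kmat, y, noise_var) {
  s2 <- max(stats::var(y), 1e-6)
  ybar <- mean(y)
  L <- chol_with_jitter(s2 * Kmat + diag(noise_var, length(y)))
  if (is.null(L)) stop("singular surrogate Gram matrix", call. = FALSE)
  list(L = L, alpha = backsolve(L, forwardsolve(t(L), y - ybar)),
       ybar = ybar, s2 = s2)
}

# EI for candidate kernel columns kx (history x candidates)
gp_ei <- function(fit, kx, f_best) {
  ks <- fit$s2 * kx
  v <- forwardsolve(t(fit$L), ks)
  mu <- fit$ybar + drop(crossprod(ks, fit$alpha))
  sd <- sqrt(pmax(fit$s2 - colSums(v^2), 0))
  ei_closed_form(mu, sd, f_best)
}

#' Size of the marker-set search space
#'
#' Exact count (in log10) of joint marker-set configurations when each of
#' `n_types` cell types independently picks between `k_min` and `k_max`
#' genes from a pool of `pool_size`:
#' `[sum_{k = k_min}^{k_max} choose(pool_size, k)] ^ n_types`.
#' Computed with exact big-integer arithmetic, so the count is not
#' limited by double precision (a 5,000-gene pool with 1-30 markers for
#' 33 types exceeds 10^83).
#'
#' @param pool_size number of candidate genes.
#' @param k_min,k_max per-type marker count bounds.
#' @param n_types number of cell types.
#' @return `log10` of the exact configuration count.
#' @examples
#' count_configurations(3, 1, 2, 2)   # log10(36)
#' @export
count_configurations <- function(pool_size, k_min, k_max, n_types) {
  stopifnot(pool_size >= k_max, k_max >= k_min, k_min >= 1, n_types >= 1)
  total <- big_zero()
  b <- big_one()                      # C(pool_size, 0)
  for (k in seq_len(k_max)) {
    b <- big_div_small(big_mul_small(b, pool_size - k + 1), k)
    if (k >= k_min) total <- big_add(total, b)
  }
  n_types * big_log10(total)
}

# --- minimal exact big-integer arithmetic (non-negative), base 1e4 limbs,
# least significant first; enough for binomial-coefficient sums ---

big_zero <- function() 0
big_one <- function() 1

big_mul_small <- function(b, m) {
  stopifnot(m >= 0, m < 2^26)
  carry <- 0
  out <- numeric(length(b))
  for (i in seq_along(b)) {
    v <- b[i] * m + carry
    out[i] <- v %% 1e4
    carry <- v %/% 1e4
  }
  while (carry > 0) {
    out <- c(out, carry %% 1e4)
    carry <- carry %/% 1e4
  }
  big_trim(out)
}

big_div_small <- function(b, d) {
  stopifnot(d >= 1, d < 2^26)
  out <- numeric(length(b))
  r <- 0
  for (i in rev(seq_along(b))) {
    cur <- r * 1e4 + b[i]
    out[i] <- cur %/% d
    r <- cur %% d
  }
  if (r != 0) stop("non-exact big-integer division", call. = FALSE)
  big_trim(out)
}

big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  out <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    v <- out[i] + carry
    out[i] <- v %% 1e4
    carry <- v %/% 1e4
  }
  if (carry > 0) out <- c(out, carry)
  big_trim(out)
}

big_trim <- function(b) {
  while (length(b) > 1 && b[length(b)] == 0) b <- b[-length(b)]
  b
}

big_log10 <- function(b) {
  nl <- length(b)
  if (nl == 1 && b[1] == 0) return(-Inf)
  top <- b[seq(nl, max(1, nl - 3))]    # most significant first
  v <- 0
  for (t in top) v <- v * 1e4 + t
  log10(v) + 4 * (nl - length(top))
}
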
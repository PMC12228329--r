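#' Similarity kernel between marker gene sets
#'
#' Two marker sets over the same cell type universe are compared by the
#' mean per-type Jaccard index of their gene lists,
#' `Jbar = mean_c |S_c intersect S'_c| / |S_c union S'_c|`, mapped
#' through an exponential: `k(S, S') = exp(-gamma * (1 - Jbar))`. The
#' kernel is symmetric, equals 1 iff the sets agree per type, and stays
#' strictly positive (fully disjoint sets give `exp(-gamma)`).
#'
#' @param S,Sp `marker_set` objects with identical cell type names.
#' @param gamma positive length-scale parameter.
#' @return similarity in `(0, 1]`.
#' @export
set_kernel <- function(S, Sp, gamma = 1) {
  stopifnot(inherits(S, "marker_set"), inherits(Sp, "marker_set"),
            gamma > 0)
  if (!setequal(names(S$sets), names(Sp$sets))) {
    stop("marker sets are over different cell type universes", call. = FALSE)
  }
  exp(-gamma * (1 - mean_jaccard(S$sets, Sp$sets)))
}

mean_jaccard <- function(a, b) {
  j <- vapply(names(a), function(nm) {
    x <- a[[nm]]; y <- b[[nm]]
    length(intersect(x, y)) / length(unique(c(x, y)))
  }, 0)
  mean(j)
}

#' Fit a Gaussian-process surrogate over marker sets
#'
#' Standard GP regression of observed objective values on marker sets
#' through the set-similarity kernel [set_kernel()]. The prior mean is
#' the mean of the observations and the signal variance is their sample
#' variance (floored to keep the posterior proper when all observations
#' coincide); observation noise `noise_var` is added on the diagonal,
#' with an escalating jitter if the Gram matrix resists Cholesky
#' factorization.
#'
#' @param history list of observations, each a list with elements `set`
#'   (a `marker_set`) and `objective` (numeric); at least 2.
#' @param gamma kernel length-scale.
#' @param noise_var observation noise variance.
#' @param signal_var prior signal variance; `NULL` (default) estimates it
#'   as the sample variance of the observations.
#' @param prior_mean constant prior mean; `NULL` (default) uses the mean
#'   of the observations.
#' @return an object of class `gp_state` with the factorized model,
#'   `f_best` (the largest observed objective) and the inputs.
#' @export
gp_fit <- function(history, gamma = 1, noise_var = 1e-4,
                   signal_var = NULL, prior_mean = NULL) {
  stopifnot(is.list(history), length(history) >= 2L,
            gamma > 0, noise_var > 0)
  sets <- lapply(history, `[[`, "set")
  y <- vapply(history, `[[`, 0, "objective")
  n <- length(y)
  K <- gram_matrix(sets, gamma)
  s2 <- signal_var %||% max(stats::var(y), 1e-6)
  ybar <- prior_mean %||% mean(y)
  Kn <- s2 * K + diag(noise_var, n)
  L <- chol_with_jitter(Kn)
  if (is.null(L)) {
    stop("kernel Gram matrix is singular even after jitter", call. = FALSE)
  }
  alpha <- backsolve(L, forwardsolve(t(L), y - ybar))
  structure(list(sets = sets, y = y, gamma = gamma, noise_var = noise_var,
                 s2 = s2, ybar = ybar, L = L, alpha = alpha,
                 f_best = max(y)),
            class = "gp_state")
}

gram_matrix <- function(sets, gamma) {
  n <- length(sets)
  K <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        K[i, j] <- K[j, i] <-
          exp(-gamma * (1 - mean_jaccard(sets[[i]]$sets, sets[[j]]$sets)))
      }
    }
  }
  K
}

chol_with_jitter <- function(Kn, tries = 6) {
  jitter <- 0
  for (t in seq_len(tries)) {
    L <- tryCatch(chol(Kn + diag(jitter, nrow(Kn))), error = function(e) NULL)
    if (!is.null(L)) return(L)
    jitter <- if (jitter == 0) 1e-10 else jitter * 100
  }
  NULL
}

#' @export
print.gp_state <- function(x, ...) {
  cat(sprintf(paste0("<gp_state> %d observations, f_best = %.4f, ",
                     "gamma = %g, noise_var = %g\n"),
              length(x$y), x$f_best, x$gamma, x$noise_var))
  invisible(x)
}

#' Posterior prediction of the GP surrogate
#'
#' @param object a `gp_state`.
#' @param newsets a `marker_set` or list of `marker_set`s.
#' @param ... unused.
#' @return data.frame with posterior `mean` and `sd` per candidate.
#' @export
predict.gp_state <- function(object, newsets, ...) {
  if (inherits(newsets, "marker_set")) newsets <- list(newsets)
  n <- length(object$y)
  out <- data.frame(mean = numeric(length(newsets)),
                    sd = numeric(length(newsets)))
  for (i in seq_along(newsets)) {
    ks <- object$s2 * vapply(object$sets, function(s) {
      exp(-object$gamma * (1 - mean_jaccard(s$sets, newsets[[i]]$sets)))
    }, 0)
    v <- forwardsolve(t(object$L), ks)
    out$mean[i] <- object$ybar + sum(ks * object$alpha)
    out$sd[i] <- sqrt(max(object$s2 - sum(v^2), 0))
  }
  out
}

#' Expected Improvement acquisition
#'
#' Expected amount by which a candidate marker set exceeds the best
#' objective observed so far, under the GP posterior:
#' `EI(S) = E[max(0, f - f_best)]`. With posterior mean `mu` and sd
#' `sigma` this has the closed form
#' `sigma * (z * Phi(z) + phi(z))`, `z = (mu - f_best) / sigma`; at
#' `sigma = 0` it degenerates to `max(0, mu - f_best)`.
#'
#' @param gp a fitted `gp_state`.
#' @param S a `marker_set` or list of `marker_set`s.
#' @return numeric EI values, all `>= 0`.
#' @export
expected_improvement <- function(gp, S) {
  stopifnot(inherits(gp, "gp_state"))
  post <- predict(gp, S)
  ei_closed_form(post$mean, post$sd, gp$f_best)
}

ei_closed_form <- function(mu, sigma, f_best) {
  out <- pmax(0, mu - f_best)
  pos <- sigma > 1e-12
  if (any(pos)) {
    z <- (mu[pos] - f_best) / sigma[pos]
    out[pos] <- sigma[pos] * (z * stats::pnorm(z) + stats::dnorm(z))
  }
  pmax(out, 0)
}
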
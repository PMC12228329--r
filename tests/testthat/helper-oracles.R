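# Independent oracles and small fixture builders used across the suite.

# Naive triple-loop enrichment scorer: the reference the vectorized
# implementation must match. Operates on a plain weighted z-score matrix.
naive_enrichment <- function(zt, sets) {
  types <- names(sets)
  out <- matrix(NA_real_, length(types), ncol(zt),
                dimnames = list(types, colnames(zt)))
  for (c in seq_along(types)) {
    genes <- intersect(sets[[c]], rownames(zt))
    for (j in seq_len(ncol(zt))) {
      s <- 0
      for (g in genes) s <- s + zt[g, j]
      out[c, j] <- s / sqrt(length(genes))
    }
  }
  out
}

# Monte-Carlo evaluation of the Expected Improvement integral
# E[max(0, f - f_best)] with f ~ N(mu, sigma^2).
mc_expected_improvement <- function(mu, sigma, f_best, n = 1e6) {
  mean(pmax(0, stats::rnorm(n, mu, sigma) - f_best))
}

# tiny dense expression matrix with named dims
tiny_matrix <- function(values, layer = "raw", genes = NULL, cells = NULL) {
  m <- as.matrix(values)
  rownames(m) <- genes %||% sprintf("g%d", seq_len(nrow(m)))
  colnames(m) <- cells %||% sprintf("c%d", seq_len(ncol(m)))
  expression_matrix(m, layer = layer)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Noise-free block fixture: one clean marker gene per type, expression 10
# in its own type's cells and 0 elsewhere, plus `extra` flat genes.
# Returned as a normalized-layer matrix (values are already on a
# log-like scale for direct z-scoring).
block_fixture <- function(n_types = 3, cells_per_type = 10, extra = 2) {
  n <- n_types * cells_per_type
  genes <- c(sprintf("mk%d", seq_len(n_types)),
             sprintf("flat%d", seq_len(extra)))
  m <- matrix(1, length(genes), n,
              dimnames = list(genes, sprintf("c%03d", seq_len(n))))
  labels <- rep(sprintf("type%d", seq_len(n_types)), each = cells_per_type)
  for (t in seq_len(n_types)) {
    m[t, labels == sprintf("type%d", t)] <- 10
  }
  sets <- as.list(sprintf("mk%d", seq_len(n_types)))
  names(sets) <- sprintf("type%d", seq_len(n_types))
  list(x = expression_matrix(m, layer = "normalized"),
       labels = stats::setNames(labels, colnames(m)),
       markers = marker_set(sets))
}
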
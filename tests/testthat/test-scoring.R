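test_that("weighted_z scales each gene row by its specificity weight", {
  Z <- tiny_matrix(matrix(c(-1, 0, 1), 1, 3), layer = "zscore",
                   genes = "g2")
  S <- marker_set(list(A = c("g1", "g2"), B = c("g2", "g3"), C = "g2"))
  # exercise theta = 0, 0.5-style and 1 weights through handmade objects
  W <- structure(list(theta = c(g2 = 0.5), occurrence = c(g2 = 2)),
                 class = "specificity_weights")
  expect_equal(unname(weighted_z(Z, W)$values[1, ]), c(-0.5, 0, 0.5))
  W0 <- structure(list(theta = c(g2 = 0), occurrence = c(g2 = 3)),
                  class = "specificity_weights")
  expect_true(all(weighted_z(Z, W0)$values == 0))
  W1 <- structure(list(theta = c(g2 = 1), occurrence = c(g2 = 1)),
                  class = "specificity_weights")
  expect_equal(weighted_z(Z, W1)$values, Z$values)
})

test_that("enrichment scores are size-normalized weighted z sums", {
  # S_c = {g1, g2}, cell with ztilde (1.0, 0.5) -> 1.5 / sqrt(2)
  Zt <- tiny_matrix(matrix(c(1.0, 0.5), 2, 1), layer = "weighted_zscore")
  S <- marker_set(list(A = c("g1", "g2")))
  E <- enrichment_scores(Zt, S)
  expect_equal(unname(E$scores["A", 1]), 1.5 / sqrt(2), tolerance = 1e-12)
  # all-zero column scores zero for every type
  Z0 <- tiny_matrix(matrix(0, 2, 1), layer = "weighted_zscore")
  expect_true(all(enrichment_scores(Z0, S)$scores == 0))
})

test_that("one type with k markers all at ztilde = z scores z * sqrt(k)", {
  for (k in c(1, 4, 9)) {
    z <- 0.7
    Zt <- tiny_matrix(matrix(z, k, 1), layer = "weighted_zscore")
    S <- marker_set(list(A = sprintf("g%d", 1:k)))
    expect_equal(unname(enrichment_scores(Zt, S)$scores["A", 1]),
                 z * sqrt(k), tolerance = 1e-12)
  }
})

test_that("vectorized scorer matches the naive triple loop exactly", {
  set.seed(11)
  for (i in 1:5) {
    m <- sample(20:100, 1)
    n <- sample(50:500, 1)
    C <- sample(2:10, 1)
    zt <- matrix(rnorm(m * n), m, n,
                 dimnames = list(sprintf("g%d", 1:m), sprintf("c%d", 1:n)))
    sets <- lapply(seq_len(C), function(i) {
      sample(rownames(zt), sample(2:10, 1))
    })
    names(sets) <- sprintf("T%02d", seq_len(C))
    E <- enrichment_scores(
      expression_matrix(zt, layer = "weighted_zscore"),
      marker_set(sets))
    expect_lt(max(abs(E$scores - naive_enrichment(zt, sets))), 1e-9)
  }
})

test_that("missing markers are dropped with rescaling; empty types NaN", {
  zt <- tiny_matrix(matrix(c(1, 1), 2, 1), layer = "weighted_zscore",
                    genes = c("g1", "g2"))
  S <- marker_set(list(A = c("g1", "g2", "gone"), B = "absent"))
  expect_warning(expect_warning(E <- enrichment_scores(zt, S), "gone"),
                 "NaN")
  # |S_A| shrinks from 3 to 2 -> 2 / sqrt(2)
  expect_equal(unname(E$scores["A", 1]), 2 / sqrt(2))
  expect_true(is.nan(E$scores["B", 1]))
  lab <- assign_labels(E)
  expect_equal(unname(lab$labels[1]), "A")  # NaN row can never win
})

test_that("label assignment takes the argmax with unknown and tie rules", {
  sc <- matrix(c(0.5, 1.2, -0.3), 3, 1,
               dimnames = list(c("A", "B", "C"), "c1"))
  E <- markeropt:::new_annotation(sc)
  expect_equal(unname(assign_labels(E)$labels), "B")
  # all scores at or below the threshold -> unknown
  E2 <- markeropt:::new_annotation(sc - 2)
  expect_equal(unname(assign_labels(E2)$labels), "unknown")
  # exact tie: lexicographically smallest type wins regardless of row order
  sc3 <- matrix(c(1, 1, 0), 3, 1, dimnames = list(c("B", "A", "C"), "c1"))
  expect_equal(unname(assign_labels(markeropt:::new_annotation(sc3))$labels),
               "A")
})

test_that("annotate recovers planted types on strongly marked data", {
  sim <- simulate_dataset(n_types = 3, cells_per_type = 120, n_genes = 500,
                          markers_per_type = 8, marker_log2fc = 3, seed = 1)
  ann <- annotate(sim$X, sim$markers)
  expect_gte(mean(ann$labels == sim$labels[names(ann$labels)]), 0.95)
})

test_that("annotation is invariant to gene row order", {
  sim <- simulate_dataset(n_types = 3, cells_per_type = 40, n_genes = 300,
                          markers_per_type = 5, seed = 3)
  ann1 <- annotate(sim$X, sim$markers)
  perm <- sample(nrow(sim$X$values))
  xp <- expression_matrix(sim$X$values[perm, ], layer = "raw")
  ann2 <- annotate(xp, sim$markers)
  expect_identical(ann1$labels, ann2$labels)
})

test_that("duplicating every cell preserves labels", {
  fx <- block_fixture()
  ann1 <- annotate(fx$x, fx$markers)
  v2 <- cbind(fx$x$values, fx$x$values)
  colnames(v2) <- sprintf("c%03d", seq_len(ncol(v2)))
  ann2 <- annotate(expression_matrix(v2, layer = "normalized"), fx$markers)
  # per-gene means and sds are recomputed on the doubled matrix (sample sd
  # changes slightly with n), but the argmax structure is unchanged
  expect_equal(unname(ann2$labels[seq_len(ncol(fx$x$values))]),
               unname(ann1$labels))
  expect_equal(unname(ann2$labels[-seq_len(ncol(fx$x$values))]),
               unname(ann1$labels))
})

test_that("marker coverage warnings and errors fire", {
  fx <- block_fixture()
  S_half <- marker_set(list(type1 = c("mk1", "nope1", "nope2"),
                            type2 = "mk2", type3 = "mk3"))
  expect_warning(annotate(fx$x, S_half), "dropped")
  S_none <- marker_set(list(A = "zz1", B = "zz2"))
  expect_error(annotate(fx$x, S_none), "none of the marker genes")
})

test_that("cluster mode assigns per cluster with the n/4 unknown rule", {
  fx <- block_fixture(n_types = 3, cells_per_type = 12)
  ann <- annotate(fx$x, fx$markers, clusters = fx$labels)
  expect_identical(unname(ann$labels), unname(fx$labels))
  # masking a type sends its whole cluster to unknown
  annm <- annotate(fx$x, mask_cell_type(fx$markers, "type1"),
                   clusters = fx$labels)
  expect_true(all(annm$labels[fx$labels == "type1"] == "unknown"))
  expect_identical(unname(annm$labels[fx$labels != "type1"]),
                   unname(fx$labels[fx$labels != "type1"]))
})
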
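test_that("folds are stratified, even and reproducible", {
  lab <- rep("A", 10)
  f <- make_folds(lab, K = 5, seed = 3)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))
  expect_identical(make_folds(lab, K = 5, seed = 3)$fold, f$fold)
  expect_false(identical(make_folds(lab, K = 5, seed = 4)$fold, f$fold))
  # a type with fewer cells than folds lands in distinct folds
  lab2 <- c(rep("A", 10), rep("B", 3))
  f2 <- make_folds(lab2, K = 5, seed = 1)
  expect_equal(length(unique(f2$fold[lab2 == "B"])), 3L)
  # stratification: each type spread as evenly as possible
  lab3 <- rep(c("A", "B"), c(20, 15))
  f3 <- make_folds(lab3, K = 5, seed = 9)
  expect_equal(as.integer(table(f3$fold[lab3 == "A"])), rep(4L, 5))
  expect_true(all(table(f3$fold[lab3 == "B"]) %in% 3L))
})

test_that("masked-type cells count as correct when predicted unknown", {
  fx <- block_fixture(n_types = 3, cells_per_type = 10)
  # clean block structure: non-masked types classify perfectly and the
  # masked type's cells all drop below the threshold -> accuracy 1
  acc <- locto_fold_accuracy(fx$x, fx$labels, fx$markers, "type1",
                             fold = seq_along(fx$labels))
  expect_equal(acc, 1)
  # a single masked-type cell correctly unknown scores 1
  one <- which(fx$labels == "type1")[1]
  expect_equal(locto_fold_accuracy(fx$x, fx$labels, fx$markers, "type1",
                                   fold = one), 1)
  # under the always-wrong rule those same cells are errors
  acc_aw <- locto_fold_accuracy(fx$x, fx$labels, fx$markers, "type1",
                                fold = seq_along(fx$labels),
                                masked_rule = "always_wrong")
  expect_equal(acc_aw, 2 / 3)
  expect_error(locto_fold_accuracy(fx$x, fx$labels, fx$markers, "type1",
                                   fold = integer(0)), "empty")
})

test_that("cv_report computes the grand mean of stubbed accuracies", {
  m <- matrix(0.8, 3, 5, dimnames = list(c("A", "B", "C"), NULL))
  expect_equal(cv_report(m)$objective, 0.8)
  m2 <- matrix(c(1, 1, 0.5, 0.5), 2, 2, dimnames = list(c("A", "B"), NULL))
  expect_equal(cv_report(m2)$objective, 0.75)
  expect_error(cv_report(matrix(1.5, 2, 2)))
})

test_that("cv_objective is a bounded deterministic grand mean", {
  sim <- simulate_dataset(n_types = 3, cells_per_type = 40, n_genes = 300,
                          markers_per_type = 5, seed = 5)
  r1 <- cv_objective(sim$X, sim$labels, sim$markers, K = 3, seed = 2)
  expect_equal(dim(r1$per_type_fold), c(3L, 3L))
  expect_equal(r1$objective, mean(r1$per_type_fold))
  expect_true(all(r1$per_type_fold >= 0 & r1$per_type_fold <= 1))
  r2 <- cv_objective(sim$X, sim$labels, sim$markers, K = 3, seed = 2)
  expect_identical(r1$per_type_fold, r2$per_type_fold)
  # invariant to cell type enumeration order in S
  S_rev <- marker_set(rev(sim$markers$sets), tissue = sim$markers$tissue)
  r3 <- cv_objective(sim$X, sim$labels, S_rev, K = 3, seed = 2)
  expect_equal(r3$objective, r1$objective)
  expect_error(cv_objective(sim$X, rep("A", length(sim$labels)),
                            sim$markers), "two cell types")
})

test_that("the planted marker set beats random markers by a wide margin", {
  sim <- simulate_dataset(n_types = 4, cells_per_type = 60, n_genes = 400,
                          markers_per_type = 6, seed = 8)
  f_true <- cv_objective(sim$X, sim$labels, sim$markers, seed = 1)$objective
  set.seed(99)
  rand_sets <- lapply(sim$markers$sets, function(s) {
    sample(gene_ids(sim$X), length(s))
  })
  f_rand <- cv_objective(sim$X, sim$labels, marker_set(rand_sets),
                         seed = 1)$objective
  expect_gt(f_true - f_rand, 0.2)
})

test_that("removing noise genes never decreases f on noiseless fixtures", {
  sim <- simulate_dataset(n_types = 3, cells_per_type = 50, n_genes = 300,
                          markers_per_type = 6, marker_log2fc = 4,
                          nb_dispersion = 100, libsize_sigma = 0, seed = 13)
  set.seed(31)
  noise <- setdiff(gene_ids(sim$X), marker_universe(sim$markers))
  for (i in 1:3) {
    aug <- lapply(sim$markers$sets, function(s) c(s, sample(noise, 2)))
    f_aug <- cv_objective(sim$X, sim$labels, marker_set(aug),
                          seed = 4)$objective
    f_clean <- cv_objective(sim$X, sim$labels, sim$markers,
                            seed = 4)$objective
    expect_gte(f_clean, f_aug)
  }
})

test_that("cv reports serialize to TSV + JSON", {
  m <- matrix(c(1, 0.5, 0.75, 0.25), 2, 2,
              dimnames = list(c("A", "B"), NULL))
  rep <- cv_report(m)
  tsv <- tempfile(fileext = ".tsv")
  write_cv_report(rep, tsv)
  long <- read.delim(tsv)
  expect_equal(nrow(long), 4L)
  expect_equal(sort(long$accuracy), c(0.25, 0.5, 0.75, 1))
  js <- jsonlite::fromJSON(sub("\\.tsv$", ".json", tsv))
  expect_equal(js$objective, 0.625)
})
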
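test_that("configuration counting matches exact enumeration", {
  # single configuration
  expect_equal(count_configurations(1, 1, 1, 1), 0)
  # (C(3,1) + C(3,2))^2 = 36
  expect_equal(count_configurations(3, 1, 2, 2), log10(36),
               tolerance = 1e-12)
  # cross-check against double-precision binomials while they are exact
  for (p in c(10, 25, 40)) {
    expect_equal(count_configurations(p, 2, 6, 3),
                 3 * log10(sum(choose(p, 2:6))), tolerance = 1e-10)
  }
  expect_error(count_configurations(5, 1, 10, 2), "pool_size")
})

test_that("big-integer helpers do exact arithmetic", {
  b <- markeropt:::big_mul_small(markeropt:::big_one(), 99991)
  b <- markeropt:::big_mul_small(b, 99991)
  expect_equal(markeropt:::big_log10(b), log10(99991^2), tolerance = 1e-12)
  expect_error(markeropt:::big_div_small(c(3), 2), "non-exact")
  s <- markeropt:::big_add(c(9999), c(2))        # 9999 + 2 = 10001
  expect_equal(s, c(1, 1))
})

em_fixture <- function() {
  fx <- block_fixture(n_types = 3, cells_per_type = 12, extra = 3)
  # add a second clean marker for type1 that is not in the current set
  v <- rbind(fx$x$values,
             mk1b = ifelse(fx$labels == "type1", 9, 1))
  list(x = expression_matrix(v, layer = "normalized"),
       labels = fx$labels,
       S = marker_set(list(type1 = c("mk1", "flat1"),
                           type2 = "mk2", type3 = "mk3")))
}

test_that("EM proposals pull in the top-statistic gene and respect bounds", {
  fx <- em_fixture()
  expect_identical(em_propose(fx$x, fx$S, 0), list())
  cands <- em_propose(fx$x, fx$S, 40, seed = 5)
  expect_length(cands, 40)
  sizes <- unlist(lapply(cands, function(S) lengths(S$sets)))
  expect_true(all(sizes >= 1 & sizes <= 30))
  # mk1b has the top specificity statistic for type1 but is absent from
  # the current set; the proposal mechanism must discover it
  expect_true(any(vapply(cands, function(S) "mk1b" %in% S$sets$type1,
                         TRUE)))
  # proposals are seeded: same seed, same candidates
  cands2 <- em_propose(fx$x, fx$S, 40, seed = 5)
  expect_identical(lapply(cands2, `[[`, "sets"),
                   lapply(cands, `[[`, "sets"))
})

test_that("a type that captures no cells keeps its markers", {
  fx <- em_fixture()
  # a marker set whose type3 list matches nothing expressed -> that type
  # never wins the argmax and is left untouched
  S <- marker_set(list(type1 = "mk1", type2 = "mk2", type3 = "flat1"))
  expect_warning(cands <- em_propose(fx$x, S, 10, seed = 2),
                 "no assigned cells")
  expect_true(all(vapply(cands, function(Sc) {
    identical(Sc$sets$type3, "flat1")
  }, TRUE)))
})

small_sim <- function() {
  simulate_dataset(n_types = 3, cells_per_type = 60, n_genes = 300,
                   markers_per_type = 5, seed = 21)
}

test_that("budget zero returns the initialized set with its objective", {
  sim <- small_sim()
  fit <- optimize_markers(sim$X, sim$labels, budget = 0, seed = 1, K = 3)
  expect_s3_class(fit, "marker_fit")
  expect_equal(nrow(fit$trace), 1L)
  expect_equal(fit$best_objective, fit$trace$objective[1])
  expect_true(fit$best_objective >= 0 && fit$best_objective <= 1)
  # data-driven initialization: half of k_max genes per type
  expect_true(all(lengths(fit$best_set$sets) == 15L))
})

test_that("optimization traces are reproducible and monotone in f_best", {
  sim <- small_sim()
  fit1 <- optimize_markers(sim$X, sim$labels, budget = 12, seed = 7, K = 3,
                           batch = 8)
  fit2 <- optimize_markers(sim$X, sim$labels, budget = 12, seed = 7, K = 3,
                           batch = 8)
  expect_identical(fit1$trace, fit2$trace)
  expect_identical(coef(fit1), coef(fit2))
  expect_true(all(diff(fit1$trace$f_best) >= 0))
  expect_equal(fit1$best_objective, max(fit1$trace$objective))
  expect_equal(fit1$best_objective, fit1$trace$f_best[nrow(fit1$trace)])
  # every evaluated set respects the bounds
  expect_true(all(unlist(lapply(fit1$history, function(h) {
    lengths(h$set$sets)
  })) <= 30))
})

test_that("the optimizer recovers planted markers on a small benchmark", {
  sim <- small_sim()
  fit <- optimize_markers(sim$X, sim$labels, budget = 40, seed = 2, K = 3,
                          batch = 16)
  rec <- planted_recovery(fit$best_set, sim$markers)
  expect_gte(rec$recall, 0.8)
  ann <- predict(fit, sim$X)
  expect_gte(mean(ann$labels == sim$labels[names(ann$labels)]), 0.9)
})

test_that("optimizer guards its inputs", {
  sim <- small_sim()
  expect_error(optimize_markers(sim$X, sim$labels, pool = c("nope"),
                                budget = 1),
               "absent")
  expect_error(optimize_markers(sim$X, sim$labels,
                                pool = gene_ids(sim$X)[1:2],
                                bounds = c(1, 2), budget = 1),
               "pool smaller")
})

test_that("fit methods expose coefficients, summaries and predictions", {
  sim <- small_sim()
  fit <- optimize_markers(sim$X, sim$labels, budget = 3, seed = 1, K = 3,
                          batch = 4)
  co <- coef(fit)
  expect_named(co, sort(unique(as.character(sim$labels))))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.marker_fit")
  expect_output(print(fit), "LOCTO")
  tmp <- tempfile(fileext = ".json")
  write_marker_fit(fit, tmp)
  js <- jsonlite::fromJSON(tmp)
  expect_equal(js$best_objective, fit$best_objective)
  expect_true(file.exists(sub("\\.json$", "_trace.tsv", tmp)))
})
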
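# Fold construction and the error-plus-size objective.

test_that("stratified k-fold splits partition the indices evenly", {
  labels <- rep(c("a", "b"), each = 5)
  folds <- kfold_split(10, labels, k = 5, seed = 1)
  expect_length(folds, 5)
  expect_setequal(unlist(folds), 1:10)
  expect_equal(sum(lengths(folds)), 10)  # disjoint + covering
  # one sample of each class per fold
  for (f in folds) {
    expect_length(f, 2)
    expect_setequal(labels[f], c("a", "b"))
  }
})

test_that("k-fold splits are deterministic in the seed and balanced on random instances", {
  for (case in 1:10) {
    n <- sample(10:40, 1)
    k <- sample(2:5, 1)
    labels <- sample(c("x", "y", "z"), n, replace = TRUE,
                     prob = c(0.5, 0.3, 0.2))
    while (any(table(labels) < 1)) labels <- sample(c("x", "y", "z"), n, TRUE)
    f1 <- suppressWarnings(kfold_split(n, labels, k, seed = case))
    f2 <- suppressWarnings(kfold_split(n, labels, k, seed = case))
    expect_identical(f1, f2)
    expect_setequal(unlist(f1), seq_len(n))
    expect_equal(sum(lengths(f1)), n)
    expect_lte(diff(range(lengths(f1))), 1)
    # per-class counts across folds differ by at most one
    for (lv in unique(labels)) {
      cnt <- vapply(f1, function(f) sum(labels[f] == lv), integer(1))
      expect_lte(diff(range(cnt)), 1)
    }
  }
})

test_that("degenerate fold requests error or reduce to singletons", {
  expect_length(kfold_split(5, rep(c("a", "b"), c(2, 3)), k = 5, seed = 1) |>
                  suppressWarnings(), 5)
  expect_error(kfold_split(4, c("a", "a", "b", "b"), k = 5), "folds")
  expect_equal(loocv_split(5), as.list(1:5))
  expect_equal(loocv_split(2), list(1L, 2L))
  expect_error(loocv_split(1), "at least 2")
})

test_that("error_rate is zero on well-separated clusters and ~0.5 on permuted labels", {
  m <- make_separable(n_per_class = 10, d = 3, n_signal = 1, shift = 20)
  cfg <- fitness_config(fold_seed = 7)
  mask <- c(TRUE, FALSE, FALSE)  # only the separating feature
  expect_equal(error_rate(mask, m, cfg), 0)

  # permutation oracle: mean error over 20 permuted-label datasets
  ers <- vapply(1:20, function(s) {
    m0 <- make_null_data(n_per_class = 20, d = 10, seed = s)
    error_rate(rep(TRUE, 10), m0, fitness_config(fold_seed = s))
  }, numeric(1))
  expect_gt(mean(ers), 0.4)
  expect_lt(mean(ers), 0.6)
})

test_that("error_rate is bit-reproducible and tie-breaks deterministically", {
  # classes are identical point sets: every prediction rides on tie-breaks,
  # which must still be reproducible run to run
  base <- matrix(rep(c(0, 1, 2, 3), each = 2), ncol = 2)
  m <- feature_matrix(rbind(base, base), rep(c("a", "b"), each = 4))
  cfg <- fitness_config(knn_k = 5, n_folds = 4, fold_seed = 11)
  e1 <- error_rate(c(TRUE, TRUE), m, cfg)
  e2 <- error_rate(c(TRUE, TRUE), m, cfg)
  expect_identical(e1, e2)

  m2 <- make_separable(n_per_class = 8, d = 4)
  cfg2 <- fitness_config(fold_seed = 3)
  expect_identical(error_rate(c(TRUE, TRUE, FALSE, FALSE), m2, cfg2),
                   error_rate(c(TRUE, TRUE, FALSE, FALSE), m2, cfg2))
})

test_that("fitness combines error and subset size with weight beta", {
  expect_equal(fitness_from_error(0.2, 50, 1000, beta = 0.99), 0.1985)
  expect_equal(fitness_from_error(0, 1000, 1000, beta = 0.99), 0.01)
  expect_equal(fitness_from_error(0.5, 0, 1000, beta = 0.99), 1)

  m <- make_separable(n_per_class = 10, d = 4, shift = 20)
  cfg <- fitness_config(fold_seed = 5)
  # ER = 0 on the separating feature: fitness is the pure size term
  expect_equal(fitness(c(TRUE, FALSE, FALSE, FALSE), m, cfg), 0.01 * 1 / 4)
  expect_equal(fitness(rep(FALSE, 4), m, cfg), 1)
  expect_error(fitness(rep(TRUE, 3), m, cfg), "length")
})

test_that("fitness is bounded, monotone in subset size at fixed error, and cacheable", {
  for (er in c(0, 0.25, 1)) {
    f <- vapply(1:10, function(s) fitness_from_error(er, s, 10), numeric(1))
    expect_true(all(f >= 0 & f <= 1))
    expect_true(all(diff(f) >= 0))
  }
  m <- make_separable(n_per_class = 6, d = 5)
  cfg <- fitness_config(fold_seed = 2)
  cache <- new_fitness_cache()
  mask <- c(TRUE, TRUE, FALSE, TRUE, FALSE)
  v1 <- fitness(mask, m, cfg, cache = cache)
  expect_length(ls(cache), 1)
  # cached value is returned verbatim
  expect_identical(fitness(mask, m, cfg, cache = cache), v1)
})

test_that("mean fitness on label-permuted data sits in the chance band", {
  fits <- vapply(1:20, function(s) {
    m0 <- make_null_data(n_per_class = 15, d = 8, seed = 100 + s)
    fitness(rep(TRUE, 8), m0, fitness_config(fold_seed = s))
  }, numeric(1))
  beta <- 0.99
  expect_gt(mean(fits), 0.4 * beta + (1 - beta))
  expect_lt(mean(fits), 0.6 * beta + (1 - beta))
})
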
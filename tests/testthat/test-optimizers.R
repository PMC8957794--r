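# The shared optimizer framework and the four update rules.

test_that("binarize uses a strict threshold and repairs empty masks", {
  expect_equal(binarize(c(0.7, 0.3, 0.5), 0.5), c(TRUE, FALSE, FALSE))
  expect_equal(binarize(rep(0.1, 4)), c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(binarize(c(0.1, 0.4, 0.2)), c(FALSE, TRUE, FALSE))
  expect_equal(binarize(rep(1, 3)), rep(TRUE, 3))
})

test_that("identical seeds give byte-identical runs; T = 1 is the initial population", {
  m <- make_separable(n_per_class = 8, d = 12)
  fit_cfg <- fitness_config(fold_seed = 4)
  for (algo in c("sma", "pfa", "hgso", "pso")) {
    cfg <- optimizer_config(algo, pop_size = 6, max_iter = 8, seed = 17)
    r1 <- swarm_optimize(m, fit_cfg, cfg)
    r2 <- swarm_optimize(m, fit_cfg, cfg)
    expect_identical(r1$trace, r2$trace, info = algo)
    expect_identical(r1$best_mask, r2$best_mask, info = algo)

    r3 <- swarm_optimize(m, fit_cfg,
                         optimizer_config(algo, pop_size = 6, max_iter = 1,
                                          seed = 17))
    expect_length(r3$trace, 1)
    expect_identical(r3$trace[1], r1$trace[1], info = algo)
  }
})

test_that("traces are monotone, bounded, and consistent with the best mask", {
  m <- make_separable(n_per_class = 8, d = 15)
  fit_cfg <- fitness_config(fold_seed = 2)
  for (algo in c("sma", "pfa", "hgso", "pso")) {
    r <- swarm_optimize(m, fit_cfg,
                        optimizer_config(algo, pop_size = 5, max_iter = 12,
                                         seed = 3))
    expect_true(all(diff(r$trace) <= 0), info = algo)
    expect_identical(r$best_fitness, r$trace[length(r$trace)], info = algo)
    expect_true(any(r$best_mask), info = algo)
    expect_true(all(r$positions >= 0 & r$positions <= 1), info = algo)
    # the reported best is reproducible by direct evaluation
    expect_equal(fitness(r$best_mask, m, fit_cfg), r$best_fitness,
                 info = algo)
  }
})

test_that("every algorithm isolates the separating signal on one-feature-separable data", {
  m <- make_separable(n_per_class = 10, d = 20, n_signal = 1, shift = 15)
  fit_cfg <- fitness_config(fold_seed = 9)
  folds <- kfold_split(20, m$labels, 5, 9)
  # oracle: direct evaluation of all 20 singleton masks bounds the optimum
  singleton_best <- min(vapply(1:20, function(j) {
    mask <- rep(FALSE, 20); mask[j] <- TRUE
    fitness(mask, m, fit_cfg, folds = folds)
  }, numeric(1)))
  expect_equal(singleton_best, 0.01 / 20)  # ER = 0 on the signal feature
  for (algo in c("sma", "pfa", "hgso", "pso")) {
    r <- swarm_optimize(m, fit_cfg,
                        optimizer_config(algo, pop_size = 10, max_iter = 60,
                                         seed = 1))
    # zero classification error with at most two features beyond the
    # singleton optimum (each extra feature costs (1 - beta)/d = 5e-4)
    expect_lte(r$best_fitness, singleton_best + 2 * 0.01 / 20 + 1e-12,
               label = paste(algo, "fitness"))
    expect_equal(error_rate(r$best_mask, m, fit_cfg, folds = folds), 0,
                 info = algo)
    expect_true(r$best_mask[1], info = algo)  # the true signal is retained
  }
})

test_that("update rules respect their fixed points and schedules", {
  d <- 6; N <- 4
  # PSO: particle sitting at gbest = pbest with zero velocity stays put
  X <- matrix(0.5, N, d)
  upd <- update_pso(X, matrix(0, N, d), X, X[1, ], t = 3, T_max = 10,
                    params = algorithm_params("pso"))
  expect_equal(upd$X, X)
  expect_equal(upd$V, matrix(0, N, d))
  # inertia schedule endpoints
  expect_equal(pso_inertia(1, 100), 0.9)
  expect_equal(pso_inertia(100, 100), 0.4)

  # PFA: whole population at the pathfinder with zeroed perturbation stays
  p <- algorithm_params("pfa"); p$u_range <- c(0, 0)
  Xp <- matrix(0.4, N, d)
  out <- update_pfa(Xp, rep(0.2, N), 1, Xp[1, ], t = 5, T_max = 10, p)
  expect_equal(out, Xp)

  # SMA with z = 1 is a pure restart: all positions resampled in [0,1]
  sma_out <- update_sma(matrix(2, N, d), rep(0.5, N), rep(0.5, d), 0.1,
                        t = 2, T_max = 10, params = list(z = 1))
  expect_true(all(sma_out >= 0 & sma_out <= 1))

  # HGSO with degenerate worst-fraction bounds reinitializes nobody
  ph <- algorithm_params("hgso"); ph$c1 <- 0; ph$c2 <- 0; ph$n_clusters <- 2
  st <- list(cluster = rep(1:2, each = 2), H = c(1e-3, 2e-3),
             P = rep(50, N), C = c(1e-2, 1e-2))
  Xh <- matrix(0.5, N, d)
  ho <- update_hgso(Xh, rep(0.3, N), st, rep(0.5, d), 0.1, t = 2, T_max = 10,
                    params = ph)
  # at a uniform population the cluster-best attraction term vanishes
  expect_equal(dim(ho$X), dim(Xh))
  expect_length(ho$state$H, 2)
})

test_that("hgso validates the cluster count", {
  m <- make_separable(n_per_class = 5, d = 6)
  expect_error(
    swarm_optimize(m, fitness_config(fold_seed = 1),
                   optimizer_config("hgso", pop_size = 3, max_iter = 2,
                                    seed = 1, params = list(n_clusters = 5))),
    "n_clusters")
})

test_that("optimization requires two classes and a clean matrix", {
  vals <- matrix(rnorm(20), 4, 5)
  one_class <- feature_matrix(vals, rep("a", 4))
  expect_error(swarm_optimize(one_class, fitness_config(),
                              optimizer_config("sma")), "two classes")
  vals[1, 1] <- NA
  dirty <- feature_matrix(vals, c("a", "a", "b", "b"))
  expect_error(swarm_optimize(dirty, fitness_config(),
                              optimizer_config("sma")), "missing")
})

test_that("write_trace emits the iteration/fitness/size table", {
  m <- make_separable(n_per_class = 5, d = 5)
  r <- swarm_optimize(m, fitness_config(fold_seed = 1),
                      optimizer_config("pso", pop_size = 4, max_iter = 5,
                                       seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_trace(r, path)
  tab <- read.delim(path)
  expect_equal(names(tab), c("iteration", "best_fitness", "n_selected"))
  expect_equal(nrow(tab), 5)
  expect_equal(tab$best_fitness, r$trace)
})
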
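# Descriptive statistics, Wilcoxon signed-rank, Friedman, selection rules.

# independent oracle: exact two-sided p by explicit enumeration of all 2^m
# sign assignments (the implementation uses rank-distribution convolution)
wilcoxon_bruteforce_p <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  rplus <- as.vector(signs %*% r)
  p_le <- mean(rplus <= obs + 1e-9)
  p_ge <- mean(rplus >= obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

test_that("describe reports n, mean, sample sd, min, max", {
  d <- describe(c(2, 4, 6))
  expect_equal(d$mean, 4)
  expect_equal(d$sd, 2)
  expect_equal(d$min, 2)
  expect_equal(d$max, 6)
  expect_equal(d$n, 3)
  expect_warning(d1 <- describe(5), "single value")
  expect_equal(d1$sd, 0)
  expect_equal(describe(rep(3.3, 8))$sd, 0)
  # permutation invariance of the summaries
  x <- rnorm(20)
  expect_equal(describe(x)[c("mean", "min", "max")],
               describe(rev(x))[c("mean", "min", "max")])
  expect_error(describe(numeric(0)), "at least one")
})

test_that("wilcoxon handles the textbook cases", {
  # all differences zero -> degenerate, p = 1
  w0 <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))
  expect_true(w0$degenerate)
  expect_equal(w0$p_value, 1)

  # diffs +1,+2,+3: R+ = 6, R- = 0, exact two-sided p = 2/8
  w <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(w$r_plus, 6)
  expect_equal(w$r_minus, 0)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 0.25)
})

test_that("rank sums always satisfy R+ + R- = m(m+1)/2", {
  with_seed(8, {
    for (case in 1:20) {
      n <- sample(3:15, 1)
      x <- round(rnorm(n), 1)  # rounding forces ties and zeros
      y <- round(rnorm(n), 1)
      if (all(x == y)) next
      w <- wilcoxon_signed_rank(x, y)
      m <- w$n_nonzero
      expect_equal(w$r_plus + w$r_minus, m * (m + 1) / 2)
    }
  })
})

test_that("exact wilcoxon p matches brute-force sign enumeration", {
  with_seed(21, {
    for (case in 1:30) {
      n <- sample(4:12, 1)
      x <- rnorm(n)
      y <- rnorm(n)
      if (case %% 3 == 0) { x <- round(x, 1); y <- round(y, 1) }  # ties
      if (all(x == y)) next
      w <- wilcoxon_signed_rank(x, y, mode = "exact")
      expect_equal(w$p_value, wilcoxon_bruteforce_p(x - y), info = case)
    }
  })
})

test_that("exact wilcoxon p agrees with stats::wilcox.test when tie-free", {
  with_seed(13, {
    for (case in 1:10) {
      n <- sample(5:12, 1)
      x <- rnorm(n); y <- rnorm(n)
      w <- wilcoxon_signed_rank(x, y, mode = "exact")
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
      expect_equal(w$p_value, unname(ref$p.value), tolerance = 1e-12)
    }
  })
})

test_that("normal-approximation mode stays close to exact p for moderate n", {
  with_seed(3, {
    x <- rnorm(20); y <- rnorm(20) + 0.3
    pe <- wilcoxon_signed_rank(x, y, mode = "exact")$p_value
    pn <- wilcoxon_signed_rank(x, y, mode = "normal")$p_value
    expect_lt(abs(pe - pn), 0.02)
  })
})

test_that("friedman matches the closed form on tie-free inputs", {
  # 10 blocks all ranking method 1 best, method 3 worst of 3
  res <- matrix(rep(c(1, 2, 3), 10), nrow = 10, byrow = TRUE)
  res <- res + matrix(runif(30, 0, 0.4), 10)  # preserve within-block order
  f <- friedman(res)
  expect_equal(f$statistic, 20)  # 12b/(k(k+1)) * sum((Rbar - 2)^2) with b=10
  expect_equal(f$df, 2)

  # closed-form equality on random tie-free matrices
  with_seed(17, {
    for (case in 1:10) {
      b <- sample(4:10, 1); k <- sample(3:5, 1)
      x <- matrix(rnorm(b * k), b, k)
      f2 <- friedman(x)
      R <- t(apply(x, 1, rank))
      closed <- 12 / (b * k * (k + 1)) * sum(colSums(R)^2) - 3 * b * (k + 1)
      expect_equal(f2$statistic, closed, tolerance = 1e-10)
      # invariance under block permutation and method relabelling
      expect_equal(friedman(x[sample(b), ])$statistic, f2$statistic)
      expect_equal(friedman(x[, sample(k)])$statistic, f2$statistic)
    }
  })
})

test_that("friedman on identical methods is 0 with p = 1", {
  x <- matrix(rep(rnorm(6), 3), ncol = 3)
  f <- friedman(x)
  expect_equal(f$statistic, 0)
  expect_equal(f$p_value, 1)
  expect_error(friedman(matrix(1:4, 4, 1)), "at least 2")
})

test_that("friedman agrees with stats::friedman.test", {
  with_seed(29, {
    x <- matrix(rnorm(8 * 3), 8, 3)
    f <- friedman(x)
    ref <- stats::friedman.test(x)
    expect_equal(f$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(f$p_value, unname(ref$p.value), tolerance = 1e-10)
  })
})

test_that("select_best applies the winner counts and tie-break rules", {
  algs <- c("P", "S", "A", "G", "Z", "H")
  dats <- paste0("d", 1:12)
  clss <- c("Q", "R")
  tab <- expand.grid(algorithm = algs, dataset = dats, classifier = clss,
                     stringsAsFactors = FALSE)
  # classifier Q strictly dominates everywhere
  tab$accuracy <- ifelse(tab$classifier == "Q", 0.8, 0.6)
  # per-dataset winners under Q: P wins d1..d8, S wins d9..d12 alone;
  # A, G, Z, H tie with S on d9..d12 via equal accuracy
  tab$accuracy[tab$classifier == "Q" & tab$algorithm == "P" &
                 tab$dataset %in% paste0("d", 1:8)] <- 0.95
  tab$accuracy[tab$classifier == "Q" & tab$algorithm != "P" &
                 tab$dataset %in% paste0("d", 9:12)] <- 0.9
  feats <- data.frame(algorithm = rep(algs, each = 2),
                      dataset = rep(c("d1", "d2"), 6),
                      n_features = rep(c(50, 40, 30, 20, 25, 10), each = 2))
  sel <- select_best(tab, feature_counts = feats)
  expect_equal(sel$best_classifier, "Q")
  # Q credited in all 72 cells (ties credit all, but Q always wins alone)
  expect_equal(unname(sel$classifier_counts["Q"]), 72)
  expect_equal(unname(sel$algorithm_counts["P"]), 8)
  # S, A, G, Z, H all tie at 4 wins; the tie-break picks the smallest
  # average selected-feature counts: H (10), then G (20)
  expect_equal(sel$top_algorithms, c("P", "H", "G"))
})

test_that("select_best rejects incomplete tables and breaks full ties lexicographically", {
  tab <- expand.grid(algorithm = c("a1", "a2"), dataset = "d1",
                     classifier = c("c1", "c2"), stringsAsFactors = FALSE)
  tab$accuracy <- 0.5
  expect_error(select_best(tab[-1, ]), "incomplete")
  sel <- select_best(tab)  # everything tied everywhere
  expect_equal(sel$best_classifier, "c1")
  expect_equal(sel$top_algorithms, c("a1", "a2"))
})
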
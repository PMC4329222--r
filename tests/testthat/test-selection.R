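test_that("CFS merit reduces to |r_cf| for singletons and follows the formula", {
  fm <- make_selection_data(1)
  y <- as.double(fm$labels)
  for (f in colnames(fm$x)) {
    expect_equal(cfs_merit(fm, f), abs(cor(fm$x[, f], y)))
  }
  pair <- c("inf1", "inf2")
  rcf <- mean(abs(cor(fm$x[, pair], y)))
  rff <- abs(cor(fm$x[, "inf1"], fm$x[, "inf2"]))
  expect_equal(cfs_merit(fm, pair), 2 * rcf / sqrt(2 + 2 * rff))
  # analytic spot value: k = 2, rcf = 0.5, rff = 0.3
  expect_equal(2 * 0.5 / sqrt(2 + 2 * 0.3), 1 / sqrt(2.6))
})

test_that("adding an uninformative feature decreases merit", {
  fm <- make_selection_data(2)
  expect_lt(cfs_merit(fm, c("inf1", "inf2", "noise1")),
            cfs_merit(fm, c("inf1", "inf2")))
})

test_that("zero-variance features score zero, not NA", {
  x <- cbind(a = rep(1, 20), b = rnorm(20))
  fm <- feature_matrix(x, rep(c(0L, 1L), 10))
  expect_equal(cfs_merit(fm, "a"), 0)
  expect_true(is.finite(cfs_merit(fm, c("a", "b"))))
})

test_that("searches recover informative features and reject noise", {
  for (seed in 1:20) {
    fm <- make_selection_data(seed)
    for (res in list(best_first_select(fm), greedy_forward_select(fm))) {
      expect_true(all(paste0("inf", 1:3) %in% res$selected),
                  info = paste("seed", seed))
      expect_false(any(paste0("noise", 1:3) %in% res$selected),
                   info = paste("seed", seed))
    }
  }
})

test_that("search merits agree with the exhaustive subset oracle", {
  for (seed in c(3, 14, 27)) {
    fm <- make_selection_data(seed)
    best <- exhaustive_best_merit(fm)
    bf <- best_first_select(fm)
    gr <- greedy_forward_select(fm)
    expect_equal(bf$merit, best, tolerance = 1e-12)
    expect_lte(gr$merit, best + 1e-12)
  }
})

test_that("a single feature is selected when it is all there is", {
  x <- matrix(rnorm(40), 20, 2)
  set.seed(6)
  x[, 1] <- rep(c(0, 3), 10) + rnorm(20, sd = 0.1)
  colnames(x) <- c("good", "bad")
  fm <- feature_matrix(x[, "good", drop = FALSE], rep(c(0L, 1L), 10))
  expect_equal(best_first_select(fm)$selected, "good")
  expect_equal(greedy_forward_select(fm)$selected, "good")
})

test_that("a duplicated informative feature is selected exactly once", {
  fm0 <- make_selection_data(4)
  x <- cbind(fm0$x, inf1_copy = fm0$x[, "inf1"])
  fm <- feature_matrix(x, fm0$labels)
  for (res in list(best_first_select(fm), greedy_forward_select(fm))) {
    expect_equal(sum(c("inf1", "inf1_copy") %in% res$selected), 1L)
  }
})

test_that("pooled-variance t ranking matches the closed form", {
  x <- cbind(f = c(1, 2, 3, 4, 5, 6))
  fm <- feature_matrix(x, c(1L, 1L, 1L, 0L, 0L, 0L))
  tr <- tstat_rank(fm)
  expect_equal(tr$t_abs, 3 / sqrt(2 / 3))

  # scale invariance
  fm2 <- feature_matrix(cbind(f = 100 * x[, 1]), fm$labels)
  expect_equal(tstat_rank(fm2)$t_abs, tr$t_abs)

  # identical class distributions
  fm3 <- feature_matrix(cbind(f = c(1, 2, 3, 1, 2, 3)),
                        c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_equal(tstat_rank(fm3)$t_abs, 0)

  # zero pooled variance with unequal means ranks first
  fm4 <- feature_matrix(cbind(a = c(0, 0, 0, 1, 1, 1), b = rnorm(6)),
                        c(1L, 1L, 1L, 0L, 0L, 0L))
  tr4 <- tstat_rank(fm4)
  expect_equal(tr4$feature[1], "a")
  expect_true(is.infinite(tr4$t_abs[1]))
})

test_that("consensus selection reaches the target attribute count", {
  set.seed(9)
  x <- matrix(rnorm(60 * 19), 60, 19)
  y <- rep(c(0L, 1L), 30)
  x[, 1:4] <- x[, 1:4] + (2 * y - 1) * 1.2
  colnames(x) <- sprintf("f%02d", 1:19)
  fm <- feature_matrix(x, y)
  sel <- select_attributes(fm, 11L)
  expect_length(sel$selected, 11L)
  expect_true(all(sprintf("f%02d", 1:4) %in% sel$selected))
})

test_that("pair search is exhaustive and returns the separable pair", {
  fm <- make_selection_data(5)
  # two candidates: the only pair comes back
  res2 <- select_pair(fm, candidates = c("inf1", "noise1"), seed = 1)
  expect_setequal(res2$pair, c("inf1", "noise1"))
  expect_equal(nrow(res2$trace), 1L)

  # trace covers all C(n, 2) combinations
  res6 <- select_pair(fm, seed = 1)
  expect_equal(nrow(res6$trace), choose(6, 2))

  # jointly separable pair recovered in >= 18/20 seeded replicates
  hits <- 0L
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    x1 <- rnorm(n); x2 <- rnorm(n)
    y <- as.integer(x1 + x2 > 0)
    x <- cbind(p1 = x1, p2 = x2, n1 = rnorm(n), n2 = rnorm(n),
               n3 = rnorm(n), n4 = rnorm(n))
    fmj <- feature_matrix(x, y)
    res <- select_pair(fmj, seed = seed)
    if (setequal(res$pair, c("p1", "p2"))) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})
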
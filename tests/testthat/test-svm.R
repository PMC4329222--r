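test_that("RBF kernel closed-form values and symmetry", {
  x <- c(1.2, -0.7, 3)
  expect_equal(rbf_kernel(x, x, sigma = 4), 1)
  a <- c(0, 0); b <- c(4, 0)  # ||a-b|| = sigma
  expect_equal(rbf_kernel(a, b, sigma = 4), exp(-1))
  set.seed(1)
  u <- rnorm(5); v <- rnorm(5)
  expect_equal(rbf_kernel(u, v, 2.5), rbf_kernel(v, u, 2.5))
  expect_error(rbf_kernel(1:2, 1:3, 1), "equal length")
  expect_error(rbf_kernel(1:2, 1:2, 0), "> 0")
})

test_that("kernel matrices are positive semi-definite", {
  set.seed(12)
  for (sigma in c(4, 32)) {
    X <- matrix(rnorm(60), 30, 2)
    K <- lungCADx:::.rbf_cross(X, X, sigma)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-9)
  }
})

test_that("separable clouds are fit to 100% training accuracy", {
  fm <- make_separable(21)
  model <- svm_train(fm, svm_config())
  pred <- predict_scan(model, fm$x)
  expect_equal(mean(pred$slice_labels == fm$labels), 1)
  # a positive-class support vector scores positive
  sv_scores <- pred$scores[fm$labels == 1L]
  expect_true(all(sv_scores > 0))
})

test_that("flipping the labels negates the decision function", {
  fm <- make_separable(22, n_per = 20L)
  cfg <- svm_config(cost_grid = 100, sigma_grid = 4, folds = 3)
  m1 <- svm_train(fm, cfg)
  m2 <- svm_train(feature_matrix(fm$x, 1L - fm$labels), cfg)
  s1 <- predict_scan(m1, fm$x)$scores
  s2 <- predict_scan(m2, fm$x)$scores
  expect_equal(s1, -s2, tolerance = 1e-6)
})

test_that("duplicating every training point leaves the boundary unchanged", {
  fm <- make_separable(23, n_per = 20L)
  cfg <- svm_config(cost_grid = 1000, sigma_grid = 4, folds = 3)
  m1 <- svm_train(fm, cfg)
  fm2 <- feature_matrix(rbind(fm$x, fm$x), c(fm$labels, fm$labels))
  m2 <- svm_train(fm2, cfg)
  grid <- as.matrix(expand.grid(f1 = seq(-4, 4, length.out = 7),
                                f2 = seq(-4, 4, length.out = 7)))
  expect_equal(predict_scan(m1, grid)$scores, predict_scan(m2, grid)$scores,
               tolerance = 1e-6)
})

test_that("a point symmetric between balanced mirrored classes scores ~0", {
  X <- rbind(c(1, 1), c(2, 0.5), c(0.5, 2),
             -c(1, 1), -c(2, 0.5), -c(0.5, 2))
  colnames(X) <- c("a", "b")
  m <- svm_train(feature_matrix(X, c(1L, 1L, 1L, 0L, 0L, 0L)),
                 svm_config(cost_grid = 100, sigma_grid = 4, folds = 3))
  expect_lt(abs(predict_slice(m, c(a = 0, b = 0))$score), 1e-9)
})

test_that("predictions are invariant to a constant feature shift", {
  fm <- make_separable(24, n_per = 15L)
  cfg <- svm_config(cost_grid = 10, sigma_grid = 4, folds = 3)
  m1 <- svm_train(fm, cfg)
  shifted <- fm$x; shifted[, "f1"] <- shifted[, "f1"] + 1000
  m2 <- svm_train(feature_matrix(shifted, fm$labels), cfg)
  test_pts <- fm$x[1:5, , drop = FALSE]
  test_shift <- shifted[1:5, , drop = FALSE]
  expect_equal(predict_scan(m1, test_pts)$scores,
               predict_scan(m2, test_shift)$scores, tolerance = 1e-9)
})

test_that("grid selection is deterministic and breaks ties toward small C, sigma", {
  fm <- make_separable(25)
  m1 <- svm_train(fm, svm_config(seed = 5))
  m2 <- svm_train(fm, svm_config(seed = 5))
  expect_identical(m1$cv_grid, m2$cv_grid)
  expect_identical(c(m1$cost, m1$sigma), c(m2$cost, m2$sigma))
  top <- m1$cv_grid[m1$cv_grid$cv_accuracy == max(m1$cv_grid$cv_accuracy), ]
  expect_equal(m1$cost, min(top$cost))
})

test_that("single-class training data is refused", {
  x <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(svm_train(feature_matrix(x, rep(1L, 10)), svm_config()),
               "both classes")
})

test_that("slice prediction demands the model's features", {
  fm <- make_separable(26, n_per = 10L)
  m <- svm_train(fm, svm_config(cost_grid = 10, sigma_grid = 4, folds = 3))
  expect_error(predict_slice(m, c(f1 = 0)), "missing feature")
  out <- predict_slice(m, c(f1 = 3, f2 = 3, extra = 9))
  expect_equal(out$label, 1L)
})

test_that("scan aggregation is a logical OR over slice decisions", {
  fm <- make_separable(27, n_per = 10L)
  m <- svm_train(fm, svm_config(cost_grid = 10, sigma_grid = 4, folds = 3))
  pos <- fm$x[fm$labels == 1L, ][1:2, ]
  neg <- fm$x[fm$labels == 0L, ][1:3, ]
  expect_equal(predict_scan(m, rbind(neg, pos[1, , drop = FALSE]))$scan_label,
               1L)
  expect_equal(predict_scan(m, neg)$scan_label, 0L)
})

test_that("JSON round trip preserves the decision function", {
  fm <- make_separable(28, n_per = 12L)
  m <- svm_train(fm, svm_config(cost_grid = 10, sigma_grid = 4, folds = 3))
  path <- tempfile(fileext = ".json")
  svm_to_json(m, path)
  m2 <- svm_from_json(path)
  expect_equal(predict_scan(m2, fm$x)$scores, predict_scan(m, fm$x)$scores,
               tolerance = 1e-9)
})
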
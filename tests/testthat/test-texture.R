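test_that("quantization bins values as specified", {
  q <- quantize(matrix(0:7, 1, 8), n_gray = 8L)
  expect_equal(as.vector(q$q), 0:7)
  expect_false(q$degenerate)

  q2 <- quantize(matrix(c(0, 3.5, 7), 1, 3), n_gray = 8L)
  expect_equal(as.vector(q2$q), c(0L, 4L, 7L))

  q3 <- quantize(matrix(2.5, 3, 3), n_gray = 8L)
  expect_true(q3$degenerate)
  expect_true(all(q3$q == 0L))

  m <- matrix(TRUE, 2, 2); m[1, 1] <- FALSE
  q4 <- quantize(matrix(c(100, 0, 1, 2), 2, 2), mask = m, n_gray = 4L)
  expect_true(is.na(q4$q[1, 1]))  # masked extreme ignored in binning
  expect_equal(q4$q[2, 1], 0L)
})

test_that("the GLCM matches the hand-enumerated toy case", {
  q <- matrix(c(0, 0, 1, 0, 1, 1, 1, 1, 1), 3, 3, byrow = TRUE)
  g <- glcm(q, 0, 1, n_gray = 2L)
  expect_equal(g$P, matrix(c(2, 2, 2, 6) / 12, 2, 2))
  expect_equal(sum(g$P), 1)
  expect_equal(g$P, t(g$P))

  const <- glcm(matrix(0L, 4, 4), 45, 1, n_gray = 3L)
  expect_equal(const$P[1, 1], 1)
  expect_equal(sum(const$P), 1)
})

test_that("GLCM agrees with brute-force pair enumeration on all small images", {
  set.seed(2024)
  for (n in 2:6) {
    for (ng in 2:4) {
      for (rep in 1:3) {
        q <- matrix(sample(0:(ng - 1), n * n, replace = TRUE), n, n)
        for (ang in c(0, 45, 90, 135)) {
          got <- glcm(q, ang, 1, n_gray = ng)$P
          expect_equal(got, brute_glcm(q, ang, 1, ng),
                       info = sprintf("n=%d ng=%d angle=%s", n, ng, ang))
        }
      }
    }
  }
})

test_that("masked pixels are excluded from pair counts", {
  q <- quantize(matrix(c(0, 0, 5, 0, 0, 5, 5, 5, 5), 3, 3, byrow = TRUE),
                mask = matrix(c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE,
                                FALSE, FALSE, FALSE), 3, 3, byrow = TRUE),
                n_gray = 2L)
  g <- glcm(q, 0, 1)
  expect_equal(g$P, matrix(c(1, 0, 0, 0), 2, 2))  # only the (0,0) pairs left
  expect_error(glcm(quantize(matrix(1, 2, 2),
                             mask = matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)),
                    0, 1),
               "zero valid")
})

test_that("marginal quantities match hand summation on the toy GLCM", {
  g <- glcm(matrix(c(0, 0, 1, 0, 1, 1, 1, 1, 1), 3, 3, byrow = TRUE),
            0, 1, n_gray = 2L)
  m <- glcm_marginals(g)
  expect_equal(m$p_sum, c(1 / 6, 1 / 3, 1 / 2))
  expect_equal(m$saver, 10 / 3)
  expect_equal(m$p_diff, c(2 / 3, 1 / 3))
  expect_equal(m$mu_diff, 1 / 3)
  expect_equal(m$px, m$py)
  expect_equal(m$mu_x, m$mu_y)
  expect_equal(m$sigma_x, m$sigma_y)
})

test_that("texture features match direct formula evaluation on the toy GLCM", {
  g <- glcm(matrix(c(0, 0, 1, 0, 1, 1, 1, 1, 1), 3, 3, byrow = TRUE),
            0, 1, n_gray = 2L)  # P = [[1/6, 1/6], [1/6, 1/2]]
  f <- compute_features(g)
  expect_equal(f[["Cont"]], 1 / 3)
  expect_equal(f[["Diss"]], 1 / 3)
  expect_equal(f[["Ener"]], sqrt(1 / 3))
  expect_equal(f[["Mp"]], 0.5)
  expect_equal(f[["Ent"]], 0.5 * log(6) + 0.5 * log(2))
  expect_equal(f[["Diffv"]], 6 / 27)
  expect_equal(f[["Sent"]], log(6) / 6 + log(3) / 3 + log(2) / 2)
  expect_equal(f[["Clsh"]], -7 / 27)
  expect_equal(f[["Autc"]], 17 / 6)
})

test_that("a constant image yields the degenerate single-cell features", {
  f <- compute_features(glcm(matrix(0L, 5, 5), 90, 1, n_gray = 8L))
  expect_equal(f[["Ener"]], 1)
  expect_equal(f[["Mp"]], 1)
  expect_equal(f[["Homo"]], 1)
  expect_equal(f[["Idm"]], 1)
  expect_equal(f[["Ent"]], 0)
  expect_equal(f[["Cont"]], 0)
  expect_equal(f[["Diss"]], 0)
  expect_equal(f[["Clsh"]], 0)
  expect_equal(f[["Corr"]], 0)
  expect_equal(f[["Imc1"]], 0)
  expect_equal(f[["Imc2"]], 0)
})

test_that("every feature is finite on random GLCMs and cross-checks hold", {
  set.seed(31)
  for (rep in 1:20) {
    q <- matrix(sample(0:7, 100, replace = TRUE), 10, 10)
    g <- glcm(q, sample(c(0, 45, 90, 135), 1), 1, n_gray = 8L)
    f <- compute_features(g)
    expect_true(all(is.finite(f)))
    expect_equal(f[["Ener"]]^2, sum(g$P^2))
    expect_equal(f[["Mp"]], max(g$P))
    expect_true(f[["Ener"]] > 0 && f[["Ener"]] <= 1)
    expect_true(f[["Imc2"]] >= 0 && f[["Imc2"]] <= 1)
    expect_true(abs(f[["Corr"]]) <= 1 + 1e-12)
  }
})

test_that("90-degree rotation swaps the partner angles exactly", {
  partner <- c("0" = 90, "45" = 135, "90" = 0, "135" = 45)
  set.seed(8)
  q <- matrix(sample(0:7, 24 * 24, replace = TRUE), 24, 24)
  qr <- lungCADx:::rot90cw(q)
  for (ang in c(0, 45, 90, 135)) {
    f_rot <- compute_features(glcm(qr, ang, 1, n_gray = 8L))
    f_par <- compute_features(glcm(q, partner[[as.character(ang)]], 1,
                                   n_gray = 8L))
    expect_equal(f_rot, f_par, tolerance = 1e-12)
  }
})

test_that("the descriptor has the documented bookkeeping dimensions", {
  s <- generate_slice(phantom_params(image_size = 64L, spacing_mm = 1,
                                     seed = 3L), TRUE)
  img <- s$image
  expect_length(extract_descriptor(img, "db1", 1, angles = 0), 76L)
  expect_length(extract_descriptor(img, "db1", 1), 304L)
  expect_length(extract_descriptor(img, c("db1", "db2", "db4"), 1), 912L)
  expect_length(extract_descriptor(img, "db1", 2, angles = 0), 133L)
  expect_length(extract_descriptor(img, c("db1", "db2", "db4"), 2), 1596L)
  d <- extract_descriptor(img, "db2", 1, angles = c(0, 90))
  expect_true(all(grepl("^db2\\.1\\.(LL|LH|HL|HH)1\\.(0|90)\\.", names(d))))
  expect_error(extract_descriptor(img, "sym4", 1), "unknown wavelet family")
})

test_that("descriptor extraction survives degenerate masked sub-bands", {
  img <- ct_image(matrix(5, 32, 32))
  roi <- circle_roi(c(16, 16), 3)
  d <- extract_descriptor(img, "db1", 2, roi = roi)
  expect_true(all(is.finite(d)))
  expect_length(d, 532L)
})
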
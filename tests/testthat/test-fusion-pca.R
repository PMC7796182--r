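table4 <- data.frame(
  strategy = c("HOG", "RotLBP", "Gabor", "GLCM", "GGCM", "HU",
               "RotLBP+HOG", "RotLBP+Gabor", "RotLBP+GLCM", "GGCM+RotLBP",
               "RotLBP+HU", "HOG+Gabor", "HOG+GLCM", "Gabor+GGCM",
               "Gabor+HU", "Gabor+GLCM", "GGCM+HU", "GGCM+HOG",
               "RotLBP+HOG+Gabor", "GGCM+RotLBP+HOG", "GLCM+RotLBP+HOG",
               "RotLBP+HOG+Gabor+GLCM", "RotLBP+HOG+Gabor+GGCM",
               "RotLBP+HOG+Gabor+HU+GGCM"),
  dim = c(324L, 160L, 360L, 6L, 15L, 8L,
          484L, 520L, 166L, 175L, 168L, 684L, 330L, 375L,
          368L, 366L, 23L, 339L, 844L, 499L, 490L, 850L, 859L, 867L))

test_that("all 24 fusion strategies reproduce the printed dimensions", {
  for (k in seq_len(nrow(table4))) {
    expect_equal(feature_dim(table4$strategy[k]), table4$dim[k],
                 info = table4$strategy[k])
  }
})

test_that("strategy parsing is case-insensitive and order-preserving", {
  a <- feature_spec("ggcm+rotlbp")
  b <- feature_spec("GGCM+RotLBP")
  expect_equal(a$descriptors, b$descriptors)
  expect_equal(feature_spec("RotLBP+GGCM")$descriptors, c("ROTLBP", "GGCM"))
  expect_error(feature_spec(""), "empty")
  expect_error(feature_spec("GGCM+SIFT"), "unknown")
})

test_that("concat_features preserves order and rejects empty input", {
  expect_equal(concat_features(list(c(1, 2), c(3))), c(1, 2, 3))
  expect_equal(concat_features(list(c(5, 6))), c(5, 6))
  expect_error(concat_features(list()), "nonempty")
})

test_that("extract_features returns the spec dimension and honors order", {
  img <- make_leaf("corn", seed = 3)
  v <- extract_features(img, "GGCM+HU")
  expect_length(v, 23L)
  w <- extract_features(img, "HU")
  expect_equal(v[16:23], w, tolerance = 1e-12)
})

test_that("full-rank PCA round-trips losslessly with orthonormal columns", {
  set.seed(10)
  X <- matrix(rnorm(30 * 5), 30, 5)
  m <- fit_pca(X, 5)
  expect_equal(crossprod(m$rotation), diag(5), tolerance = 1e-10)
  Xhat <- apply_pca(m, X) %*% t(m$rotation) + rep(1, 30) %o% m$mean
  expect_equal(Xhat, X, tolerance = 1e-8)
})

test_that("the leading direction of an elongated cloud is recovered", {
  set.seed(2)
  t <- rnorm(500, sd = 4)
  X <- cbind(t + rnorm(500, sd = 0.3), t + rnorm(500, sd = 0.3))
  m <- fit_pca(X, 1)
  ang <- acos(abs(sum(m$rotation[, 1] * c(1, 1) / sqrt(2)))) * 180 / pi
  expect_lt(ang, 1)
})

test_that("apply_pca matches the direct (x - mean) %*% rotation product", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40, 6)
  m <- fit_pca(X, 3)
  x <- rnorm(6)
  expect_equal(as.vector(apply_pca(m, x)),
               as.vector((x - m$mean) %*% m$rotation), tolerance = 1e-12)
  # training scores are reproduced on re-application
  expect_equal(apply_pca(m, X), apply_pca(m, X))
  expect_error(apply_pca(m, matrix(0, 2, 5)), "mismatch")
})

test_that("zero-variance columns carry no loading and variance never grows", {
  set.seed(6)
  X <- cbind(matrix(rnorm(50 * 3), 50, 3), 7)
  m <- fit_pca(X, 3)
  expect_true(all(abs(m$rotation[4, ]) < 1e-10))
  expect_lte(sum(apply(apply_pca(m, X), 2, var)), sum(apply(X, 2, var)) + 1e-10)
  expect_error(fit_pca(X, 0), "out of range")
  expect_error(fit_pca(X, 5), "out of range")
})

test_that("select_retention picks the smallest dimension reaching peak accuracy", {
  set.seed(8)
  n <- 200
  y <- rep(c(1L, -1L), n / 2)
  noise_dim <- 4
  X <- cbind(3 * rnorm(n),                  # high-variance, uninformative
             2.5 * y + rnorm(n, sd = 0.3),  # informative, second-largest variance
             matrix(rnorm(n * noise_dim, sd = 0.1), n, noise_dim))
  single <- select_retention(X, y, candidates = 3L)
  expect_equal(single$p, 3L)
  for (seed in 0:2) {
    sel <- select_retention(X, y, candidates = c(1L, 2L, 4L, 6L), seed = seed)
    expect_true(sel$p %in% c(1L, 2L, 4L, 6L))
    expect_equal(sel$p, 2L)
  }
})
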
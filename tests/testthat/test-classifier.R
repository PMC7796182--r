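make_blobs <- function(n_per_class, sep = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per_class * 2), ncol = 2) + sep / 2,
             matrix(rnorm(n_per_class * 2), ncol = 2) - sep / 2)
  list(X = X, y = rep(c(1L, -1L), each = n_per_class))
}

test_that("the 70/30 stratified split reproduces the 700/300 protocol", {
  labels <- rep(c(1L, -1L), each = 1000)
  idx <- split_dataset(labels, 0.7, seed = 3)
  expect_equal(sum(labels[idx$train] == 1), 700)
  expect_equal(sum(labels[idx$train] == -1), 700)
  expect_equal(sum(labels[idx$validation] == 1), 300)
  expect_equal(sum(labels[idx$validation] == -1), 300)
})

test_that("splits are deterministic, disjoint, and exhaustive", {
  labels <- rep(c(1L, -1L), times = c(40, 25))
  a <- split_dataset(labels, 0.7, seed = 11)
  b <- split_dataset(labels, 0.7, seed = 11)
  expect_identical(a, b)
  expect_length(intersect(a$train, a$validation), 0)
  expect_setequal(c(a$train, a$validation), seq_along(labels))
  # class balance preserved within rounding
  expect_equal(sum(labels[a$train] == 1), round(0.7 * 40))
  expect_equal(sum(labels[a$train] == -1), round(0.7 * 25))
  expect_error(split_dataset(rep(1L, 10), 0.7, seed = 1), "classes")
  expect_error(split_dataset(labels, 1.2, seed = 1), "train_fraction")
})

test_that("linearly separable blobs are fit perfectly; contradictions are not", {
  d <- make_blobs(40)
  m <- train_svm(d$X, d$y)
  expect_equal(evaluate(m, d$X, d$y)$accuracy, 1.0)
  # identical features with opposite labels: irreducible error
  Xc <- rbind(d$X, d$X)
  yc <- c(d$y, -d$y)
  mc <- train_svm(Xc, yc)
  expect_lte(evaluate(mc, Xc, yc)$accuracy, 0.5)
  expect_error(train_svm(d$X, rep(1L, nrow(d$X))), "classes")
  expect_error(train_svm(d$X, rep(c(0L, 1L), 40)), "labels")
})

test_that("accuracy follows (TP+TN)/(TP+FP+FN+TN) and a per-sample recount", {
  expect_equal(accuracy_from_counts(c(TP = 50, FP = 3, FN = 2, TN = 45)), 0.95)
  d <- make_blobs(30, sep = 2, seed = 4)
  m <- train_svm(d$X, d$y)
  ev <- evaluate(m, d$X, d$y)
  pred <- predict(m, d$X)
  recount <- c(TP = 0, FP = 0, FN = 0, TN = 0)
  for (i in seq_along(d$y)) {
    key <- if (d$y[i] == 1 && pred[i] == 1) "TP"
      else if (d$y[i] == -1 && pred[i] == 1) "FP"
      else if (d$y[i] == 1 && pred[i] == -1) "FN"
      else "TN"
    recount[key] <- recount[key] + 1
  }
  expect_equal(ev$counts, recount)
  expect_equal(ev$accuracy, mean(pred == d$y))
  expect_equal(sum(ev$counts), length(d$y))
})

test_that("prediction is invariant to validation ordering and survives save/load", {
  d <- make_blobs(25, sep = 3, seed = 7)
  m <- train_svm(d$X, d$y)
  perm <- sample(nrow(d$X))
  expect_equal(predict(m, d$X)[perm], predict(m, d$X[perm, ]))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  probe <- matrix(rnorm(20), 10, 2)
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_equal(predict(m, probe, decision = TRUE), predict(m2, probe, decision = TRUE))
})

test_that("decision values are positive toward corn on separated data", {
  d <- make_blobs(30, sep = 8, seed = 2)
  m <- train_svm(d$X, d$y)
  sc <- predict(m, d$X, decision = TRUE)
  expect_true(all(sc[d$y == 1] > 0))
  expect_true(all(sc[d$y == -1] < 0))
})

test_that("repeat_experiment is reproducible and consistent with single runs", {
  d <- make_blobs(60, sep = 1.5, seed = 9)
  one <- repeat_experiment(d$X, d$y, seeds = 5L)
  expect_equal(one$mean_accuracy, one$runs$accuracy[1])
  ten_a <- repeat_experiment(d$X, d$y, seeds = 0:9)
  ten_b <- repeat_experiment(d$X, d$y, seeds = 0:9)
  expect_identical(ten_a$runs, ten_b$runs)
  expect_equal(ten_a$mean_accuracy, mean(ten_a$runs$accuracy))
  expect_true(all(ten_a$runs$accuracy >= 0 & ten_a$runs$accuracy <= 1))
})
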
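# SVM leaf classifier: stratified split, training, evaluation, repetition.

#' Stratified train/validation split
#'
#' Shuffles sample order with the given seed and assigns, per class, a
#' `train_fraction` share to training (rounded to the nearest integer),
#' the remainder to validation. With 1000 samples per class at 0.7 this
#' gives the 700/300 per-class protocol.
#'
#' @param labels Vector of class labels (+1 corn / -1 weed).
#' @param train_fraction Fraction of each class assigned to training.
#' @param seed Integer seed; the same seed reproduces the same split.
#' @return List with integer index vectors `train` and `validation`.
#' @export
split_dataset <- function(labels, train_fraction = 0.7, seed = 0L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  classes <- unique(labels)
  if (length(classes) < 2L)
    stop("both classes must be present", call. = FALSE)
  idx <- with_seed(seed, {
    tr <- integer(0)
    for (cl in sort(classes)) {
      members <- which(labels == cl)
      n_tr <- round(train_fraction * length(members))
      if (n_tr < 1L || n_tr >= length(members))
        stop("class too small for this split", call. = FALSE)
      tr <- c(tr, sample(members, n_tr))
    }
    tr
  })
  list(train = sort(idx), validation = setdiff(seq_along(labels), idx))
}

#' Train the SVM leaf classifier
#'
#' Standardizes each feature dimension with training-set statistics
#' (fused descriptors have very different magnitudes) and fits a support
#' vector machine on the +1 (corn) / -1 (weed) labels. The returned
#' bundle carries everything needed to classify new images identically:
#' the scaler, an optional PCA projection, and the feature spec.
#'
#' @param X Feature (or PCA-score) matrix, samples in rows.
#' @param y Labels, +1 for corn and -1 for weed.
#' @param kernel SVM kernel, `"linear"` (default) or `"radial"`.
#' @param cost Soft-margin cost parameter.
#' @param gamma RBF kernel width (ignored for linear).
#' @param spec Optional `feature_spec` used to produce `X`.
#' @param pca Optional `pca_model` applied before `X`.
#' @return Object of class `weed_model`.
#' @export
train_svm <- function(X, y, kernel = c("linear", "radial"), cost = 1,
                      gamma = NULL, spec = NULL, pca = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  y <- as.integer(y)
  if (!all(y %in% c(-1L, 1L))) stop("labels must be +1 or -1", call. = FALSE)
  if (length(unique(y)) < 2L) stop("both classes must be present", call. = FALSE)
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  args <- list(x = Xs, y = factor(y, levels = c(-1L, 1L)),
               kernel = kernel, cost = cost, scale = FALSE)
  if (kernel == "radial" && !is.null(gamma)) args$gamma <- gamma
  fit <- do.call(e1071::svm, args)
  structure(list(svm = fit, center = ctr, scale = scl,
                 pca = pca, spec = spec, kernel = kernel, cost = cost),
            class = "weed_model")
}

#' @export
print.weed_model <- function(x, ...) {
  cat(sprintf("weed_model: %s SVM on %d features (%d support vectors)\n",
              x$kernel, length(x$center), x$svm$tot.nSV))
  if (!is.null(x$spec)) print(x$spec)
  if (!is.null(x$pca)) print(x$pca)
  invisible(x)
}

#' Predict labels for prepared feature rows
#'
#' Applies the bundled PCA projection (if any), the training-set scaler,
#' and the SVM. Input rows must be raw fused features when the bundle
#' holds a PCA model, or PCA scores otherwise.
#'
#' @param object A `weed_model`.
#' @param newdata Matrix of samples in rows (or a single vector).
#' @param decision If `TRUE`, return the signed decision values instead
#'   of labels.
#' @param ... Unused.
#' @return Integer labels (+1 corn / -1 weed) or decision values.
#' @export
predict.weed_model <- function(object, newdata, decision = FALSE, ...) {
  X <- if (is.vector(newdata)) matrix(newdata, nrow = 1L) else as.matrix(newdata)
  if (!is.null(object$pca) && ncol(X) == length(object$pca$mean))
    X <- apply_pca(object$pca, X)
  if (ncol(X) != length(object$center))
    stop("feature dimension mismatch", call. = FALSE)
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  pr <- stats::predict(object$svm, Xs, decision.values = TRUE)
  if (decision) {
    dv <- attr(pr, "decision.values")
    # e1071 orients the decision value by factor level order; flip so
    # positive means corn (+1).
    sgn <- if (grepl("^-1", colnames(dv)[1])) -1 else 1
    return(as.numeric(dv[, 1]) * sgn)
  }
  as.integer(as.character(pr))
}

#' Classify a single leaf image
#'
#' Runs the model's full feature pipeline (spec extraction, PCA, scaling,
#' SVM) on one raster.
#'
#' @param model A `weed_model` whose bundle includes a `feature_spec`.
#' @param img Raster image.
#' @return List with `label` (+1/-1), `class` (`"corn"`/`"weed"`) and
#'   `score` (signed decision value, positive toward corn).
#' @export
classify_image <- function(model, img) {
  if (is.null(model$spec)) stop("model bundle has no feature_spec", call. = FALSE)
  v <- extract_features(img, model$spec)
  lab <- predict(model, v)
  sc <- predict(model, v, decision = TRUE)
  list(label = lab, class = if (lab > 0) "corn" else "weed", score = sc)
}

#' Evaluate a model on a validation set
#'
#' Computes the confusion counts with corn (+1) as the positive class --
#' TP: corn detected as corn; FP: weed detected as corn; FN: corn
#' detected as weed; TN: weed detected as weed -- and the accuracy
#' `(TP + TN) / (TP + FP + FN + TN)`.
#'
#' @param model A `weed_model`.
#' @param X Validation features (matching what the model expects).
#' @param y True labels (+1/-1).
#' @return List with `counts` (named TP, FP, FN, TN) and `accuracy`.
#' @export
evaluate <- function(model, X, y) {
  if (length(y) == 0L) stop("validation set is empty", call. = FALSE)
  pred <- predict(model, X)
  y <- as.integer(y)
  counts <- c(TP = sum(pred == 1L & y == 1L),
              FP = sum(pred == 1L & y == -1L),
              FN = sum(pred == -1L & y == 1L),
              TN = sum(pred == -1L & y == -1L))
  list(counts = counts, accuracy = accuracy_from_counts(counts))
}

#' Accuracy from confusion counts
#'
#' @param counts Named vector or list with TP, FP, FN, TN.
#' @return `(TP + TN) / (TP + FP + FN + TN)`.
#' @export
accuracy_from_counts <- function(counts) {
  counts <- as.list(counts)
  (counts$TP + counts$TN) / (counts$TP + counts$FP + counts$FN + counts$TN)
}

#' Repeat the split/train/validate experiment
#'
#' Runs the full protocol once per seed -- optional PCA on the full
#' feature matrix, stratified 70/30 split, SVM training, hold-out
#' evaluation -- and reports per-run and mean accuracy, the layout used
#' to compare fusion strategies over 10 repetitions.
#'
#' @param X Fused feature matrix, samples in rows.
#' @param y Labels (+1/-1).
#' @param seeds Integer seeds, one run per seed (default `0:9`).
#' @param train_fraction Training share per class.
#' @param pca_dim Retained PCA dimension, or `NULL` to skip reduction.
#'   Reduction is also skipped when the feature dimension is 15 or less.
#' @param kernel,cost Passed to [train_svm()].
#' @return List with `runs` (data.frame seed/accuracy) and `mean_accuracy`.
#' @export
repeat_experiment <- function(X, y, seeds = 0:9, train_fraction = 0.7,
                              pca_dim = NULL, kernel = "linear", cost = 1) {
  if (length(seeds) < 1L) stop("need at least one seed", call. = FALSE)
  X <- as.matrix(X)
  scores <- X
  pca <- NULL
  if (!is.null(pca_dim) && ncol(X) > 15L && pca_dim < ncol(X)) {
    pca <- fit_pca(X, pca_dim)
    scores <- apply_pca(pca, X)
  }
  acc <- vapply(seeds, function(s) {
    idx <- split_dataset(y, train_fraction = train_fraction, seed = s)
    m <- train_svm(scores[idx$train, , drop = FALSE], y[idx$train],
                   kernel = kernel, cost = cost)
    evaluate(m, scores[idx$validation, , drop = FALSE], y[idx$validation])$accuracy
  }, numeric(1))
  list(runs = data.frame(seed = seeds, accuracy = acc),
       mean_accuracy = mean(acc), pca = pca)
}

#' Save / load a model bundle
#'
#' The bundle (SVM, scaler, PCA model, feature spec) is serialized with
#' `saveRDS`; the feature spec is additionally written as a JSON sidecar
#' for inspection. Reloaded models predict identically.
#'
#' @param model A `weed_model`.
#' @param path Destination `.rds` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  if (!is.null(model$spec))
    spec_to_json(model$spec, paste0(tools::file_path_sans_ext(path), "_spec.json"))
  invisible(path)
}

#' @rdname save_model
#' @return For `load_model`, the restored `weed_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "weed_model")) stop("not a weed_model bundle", call. = FALSE)
  m
}
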
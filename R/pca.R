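# Principal-component reduction with a reusable projection.

#' Fit a PCA projection
#'
#' Mean-centers the sample-by-dimension matrix and computes the top `p`
#' principal directions by descending variance (via SVD). The projection
#' columns are orthonormal and carry a deterministic sign convention: the
#' largest-magnitude loading of each component is positive, so repeated
#' fits on the same data give identical models. The stored mean and
#' `input-dim x p` projection are applied identically to training,
#' validation, and field-region features.
#'
#' @param X Numeric matrix, samples in rows.
#' @param p Number of components to retain, `1 <= p <= min(nrow - 1, ncol)`.
#' @return Object of class `pca_model`: list with `mean`, `rotation`
#'   (`ncol(X) x p`, orthonormal), `p`, `sdev`.
#' @export
fit_pca <- function(X, p) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  p <- as.integer(p)
  if (p < 1L || p > min(nrow(X) - 1L, ncol(X)))
    stop("p out of range: need 1 <= p <= min(samples - 1, dim)", call. = FALSE)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  sv <- svd(Xc, nu = 0, nv = p)
  rot <- sv$v[, seq_len(p), drop = FALSE]
  for (k in seq_len(p)) {
    if (rot[which.max(abs(rot[, k])), k] < 0) rot[, k] <- -rot[, k]
  }
  structure(list(mean = mu, rotation = rot, p = p,
                 sdev = sv$d[seq_len(p)] / sqrt(max(1, nrow(X) - 1L))),
            class = "pca_model")
}

#' Apply a fitted PCA projection
#'
#' Computes `(X - mean) %*% rotation`, the same mapping for any data that
#' shares the training feature layout.
#'
#' @param model A `pca_model`.
#' @param X Numeric matrix (or single vector) with `length(model$mean)`
#'   columns.
#' @return Matrix of scores with `model$p` columns.
#' @export
apply_pca <- function(model, X) {
  if (!inherits(model, "pca_model")) stop("model must be a pca_model", call. = FALSE)
  if (is.vector(X)) X <- matrix(X, nrow = 1L)
  if (ncol(X) != length(model$mean))
    stop("dimension mismatch: expected ", length(model$mean), " columns", call. = FALSE)
  sweep(X, 2L, model$mean) %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d -> %d dimensions\n", length(x$mean), x$p))
  invisible(x)
}

#' Select the PCA retention with highest validation accuracy
#'
#' Runs the evaluation function for each candidate retained-dimension and
#' returns the candidate with the highest accuracy; ties go to the
#' smallest `p` (parsimony).
#'
#' @param X Feature matrix, samples in rows.
#' @param y Labels (+1 corn / -1 weed).
#' @param candidates Integer vector of retention counts to try.
#' @param eval_fn Function `(scores, y, p) -> accuracy`; the default
#'   fits a linear SVM on a stratified 70/30 split and reports hold-out
#'   accuracy.
#' @param seed Seed for the default evaluation split.
#' @return List with `p` (selected retention) and `accuracy` (per
#'   candidate, named).
#' @export
select_retention <- function(X, y, candidates, eval_fn = NULL, seed = 0L) {
  if (length(candidates) == 0L) stop("candidates must be nonempty", call. = FALSE)
  candidates <- sort(unique(as.integer(candidates)))
  if (is.null(eval_fn)) {
    eval_fn <- function(scores, y, p) {
      idx <- split_dataset(y, train_fraction = 0.7, seed = seed)
      m <- train_svm(scores[idx$train, , drop = FALSE], y[idx$train])
      evaluate(m, scores[idx$validation, , drop = FALSE], y[idx$validation])$accuracy
    }
  }
  acc <- vapply(candidates, function(p) {
    scores <- apply_pca(fit_pca(X, p), X)
    eval_fn(scores, y, p)
  }, numeric(1))
  names(acc) <- candidates
  list(p = candidates[which.max(acc)], accuracy = acc)
}
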
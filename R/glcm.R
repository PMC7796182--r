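# Gray-level co-occurrence matrix and its six texture statistics.

#' Displacement vector for a co-occurrence direction
#'
#' Maps the conventional angles to a unit `(delta_row, delta_col)`
#' displacement: 0 degrees is the horizontal neighbor `d = (1, 0)` in
#' (x, y) notation, i.e. `(0, 1)` in (row, col).
#'
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @return Integer `c(delta_row, delta_col)`.
#' @export
glcm_offset <- function(angle = 0) {
  switch(as.character(angle),
         "0"   = c(0L, 1L),
         "45"  = c(-1L, 1L),
         "90"  = c(-1L, 0L),
         "135" = c(-1L, -1L),
         stop("angle must be one of 0, 45, 90, 135", call. = FALSE))
}

#' Gray-level co-occurrence matrix
#'
#' Quantizes the image to `levels` gray bins and counts ordered pixel
#' pairs `(i, j)` separated by `offset`; the matrix is normalized by the
#' total pair count `N`, so `P(i, j) = C(i, j) / N` sums to 1. Defaults
#' follow the common texture setup for leaf images: 64 gray levels and
#' the 0-degree displacement.
#'
#' @param img Grayscale matrix, values in `[0, 255]`.
#' @param levels Number of gray quantization levels (default 64).
#' @param offset Integer `c(delta_row, delta_col)` displacement.
#' @return Object of class `glcm`: list with `P` (levels x levels,
#'   sums to 1), `counts`, `n_pairs`, `levels`, `offset`.
#' @export
glcm <- function(img, levels = 64L, offset = c(0L, 1L)) {
  check_raster(img, channels = 1L)
  levels <- as.integer(levels)
  if (levels < 2L) stop("levels must be >= 2", call. = FALSE)
  offset <- as.integer(offset)
  if (all(offset == 0L)) stop("offset must be nonzero", call. = FALSE)
  h <- img_height(img); w <- img_width(img)
  dr <- offset[1]; dc <- offset[2]
  r1 <- max(1L, 1L - dr):min(h, h - dr)
  c1 <- max(1L, 1L - dc):min(w, w - dc)
  if (max(1L, 1L - dr) > min(h, h - dr) || max(1L, 1L - dc) > min(w, w - dc))
    stop("image contains no pixel pairs at this offset", call. = FALSE)
  q <- quantize_gray(img, levels)
  i <- q[r1, c1, drop = FALSE]
  j <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(tabulate(as.vector(i) * levels + as.vector(j) + 1L,
                            nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  n <- length(i)
  structure(list(P = counts / n, counts = counts, n_pairs = n,
                 levels = levels, offset = offset),
            class = "glcm")
}

#' Six co-occurrence texture statistics
#'
#' Computes, in order: energy (angular second moment), contrast,
#' correlation, sum entropy, entropy, and inverse difference moment.
#' Entropies use the natural logarithm with the 0 log 0 = 0 convention,
#' so a texture-free (single-entry) matrix has zero entropy. Correlation
#' is guarded to 0 when either marginal variance vanishes.
#'
#' @param P A `glcm` object or a normalized co-occurrence matrix.
#' @return Named numeric vector of length 6.
#' @export
glcm_stats <- function(P) {
  if (inherits(P, "glcm")) P <- P$P
  if (!is.matrix(P) || abs(sum(P) - 1) > 1e-8)
    stop("P must be a normalized co-occurrence matrix", call. = FALSE)
  g <- nrow(P)
  iv <- 0:(g - 1L)
  i <- matrix(iv, g, g)
  j <- matrix(iv, g, g, byrow = TRUE)

  energy <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  var_i <- sum((i - mu_i)^2 * P); var_j <- sum((j - mu_j)^2 * P)
  correlation <- if (var_i > 0 && var_j > 0)
    sum((i - mu_i) * (j - mu_j) * P) / sqrt(var_i * var_j) else 0
  psum <- tapply(as.vector(P), as.vector(i + j), sum)
  sum_entropy <- -sum(psum[psum > 0] * log(psum[psum > 0]))
  entropy <- -sum(P[P > 0] * log(P[P > 0]))
  idm <- sum(P / (1 + (i - j)^2))

  c(energy = energy, contrast = contrast, correlation = correlation,
    sum_entropy = sum_entropy, entropy = entropy, idm = idm)
}
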
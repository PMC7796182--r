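# Gray level-gradient co-occurrence matrix and its 15 statistics.

# Sobel gradient magnitude with edge-replicated borders.
sobel_magnitude <- function(img) {
  p <- pad_replicate1(img)
  h <- nrow(img); w <- ncol(img)
  right <- p[2:(h + 1L), 3:(w + 2L)]; left <- p[2:(h + 1L), 1:w]
  down <- p[3:(h + 2L), 2:(w + 1L)]; up <- p[1:h, 2:(w + 1L)]
  dr_ <- p[3:(h + 2L), 3:(w + 2L)]; dl_ <- p[3:(h + 2L), 1:w]
  ur_ <- p[1:h, 3:(w + 2L)]; ul_ <- p[1:h, 1:w]
  gx <- (ur_ + 2 * right + dr_) - (ul_ + 2 * left + dl_)
  gy <- (dl_ + 2 * down + dr_) - (ul_ + 2 * up + ur_)
  sqrt(gx^2 + gy^2)
}

#' Gray level-gradient co-occurrence matrix
#'
#' Joint histogram of quantized gray level and quantized Sobel gradient
#' magnitude over all pixels: texture information from both the intensity
#' distribution and the intensity *changes* (edges, vein boundaries).
#' Gray values are quantized to `gray_levels` bins on the fixed `[0,255]`
#' scale; gradient magnitudes are max-normalized before quantization to
#' `grad_levels` bins (an image with no gradient puts all mass in
#' gradient level 0).
#'
#' @param img Grayscale matrix, at least 3x3.
#' @param gray_levels Gray quantization levels (default 64).
#' @param grad_levels Gradient quantization levels (default 64).
#' @return Object of class `ggcm`: list with `counts`
#'   (gray_levels x grad_levels), normalized `P` (sums to 1), `n_pixels`,
#'   `gray_levels`, `grad_levels`.
#' @export
ggcm <- function(img, gray_levels = 64L, grad_levels = 64L) {
  check_raster(img, channels = 1L)
  if (img_height(img) < 3L || img_width(img) < 3L)
    stop("image must be at least 3x3 for the gradient operator", call. = FALSE)
  gray_levels <- as.integer(gray_levels); grad_levels <- as.integer(grad_levels)
  gq <- quantize_gray(img, gray_levels)
  grad <- sobel_magnitude(img)
  gmax <- max(grad)
  sq <- if (gmax > 0) pmin(floor(grad / gmax * grad_levels), grad_levels - 1L)
        else matrix(0L, nrow(img), ncol(img))
  counts <- matrix(tabulate(as.vector(gq) * grad_levels + as.vector(sq) + 1L,
                            nbins = gray_levels * grad_levels),
                   gray_levels, grad_levels, byrow = TRUE)
  n <- length(img)
  structure(list(counts = counts, P = counts / n, n_pixels = n,
                 gray_levels = gray_levels, grad_levels = grad_levels),
            class = "ggcm")
}

#' Fifteen gray-gradient co-occurrence statistics
#'
#' The standard gray-gradient statistic set: small gradient dominance,
#' large gradient dominance, gray distribution nonuniformity, gradient
#' distribution nonuniformity, energy, gray mean, gradient mean, gray
#' mean square error, gradient mean square error, correlation, gray
#' entropy, gradient entropy, mixed entropy, inertia, and inverse
#' difference (deficit) moment. Levels enter the formulas 1-based (level
#' index 1..G), entropies use the natural logarithm, and correlation is
#' the gray-gradient covariance.
#'
#' @param H A `ggcm` object.
#' @return Named numeric vector of length 15.
#' @export
ggcm_stats <- function(H) {
  if (!inherits(H, "ggcm")) stop("H must be a ggcm object", call. = FALSE)
  C <- H$counts
  n <- H$n_pixels
  P <- H$P
  gi <- seq_len(H$gray_levels)    # gray level index, 1-based
  sj <- seq_len(H$grad_levels)    # gradient level index, 1-based
  I <- matrix(gi, H$gray_levels, H$grad_levels)
  J <- matrix(sj, H$gray_levels, H$grad_levels, byrow = TRUE)

  row_c <- rowSums(C); col_c <- colSums(C)
  p_i <- rowSums(P); p_j <- colSums(P)

  small_grad <- sum(sweep(C, 2L, sj^2, "/")) / n
  large_grad <- sum(sweep(C, 2L, sj^2, "*")) / n
  gray_nonunif <- sum(row_c^2) / n
  grad_nonunif <- sum(col_c^2) / n
  energy <- sum(P^2)
  gray_mean <- sum(gi * p_i)
  grad_mean <- sum(sj * p_j)
  gray_mse <- sqrt(sum((gi - gray_mean)^2 * p_i))
  grad_mse <- sqrt(sum((sj - grad_mean)^2 * p_j))
  correlation <- sum((I - gray_mean) * (J - grad_mean) * P)
  gray_entropy <- -sum(p_i[p_i > 0] * log(p_i[p_i > 0]))
  grad_entropy <- -sum(p_j[p_j > 0] * log(p_j[p_j > 0]))
  mixed_entropy <- -sum(P[P > 0] * log(P[P > 0]))
  inertia <- sum((I - J)^2 * P)
  deficit <- sum(P / (1 + (I - J)^2))

  c(small_gradient_dominance = small_grad,
    large_gradient_dominance = large_grad,
    gray_nonuniformity = gray_nonunif,
    gradient_nonuniformity = grad_nonunif,
    energy = energy,
    gray_mean = gray_mean,
    gradient_mean = grad_mean,
    gray_mse = gray_mse,
    gradient_mse = grad_mse,
    correlation = correlation,
    gray_entropy = gray_entropy,
    gradient_entropy = grad_entropy,
    mixed_entropy = mixed_entropy,
    inertia = inertia,
    deficit_moment = deficit)
}
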
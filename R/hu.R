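# Hu invariant moments (seven classical invariants plus an eighth).

#' Hu moment invariants (eight values)
#'
#' Treats the grayscale image as a 2-D intensity distribution, computes
#' normalized central moments eta_pq = mu_pq / mu_00^(1 + (p+q)/2), and
#' returns the seven classical Hu invariants phi1..phi7 together with the
#' eighth invariant
#' phi8 = 2 eta11 ((eta30 + eta12)^2 - (eta03 + eta21)^2)
#'        - 2 (eta20 - eta02)(eta30 + eta12)(eta21 + eta03).
#' All eight are invariant to translation of content within the frame;
#' phi1..phi7 are additionally invariant (up to discretization) to scale.
#' phi8 vanishes for images with four-fold mirror symmetry.
#'
#' @param img Grayscale matrix with nonzero total intensity.
#' @return Named numeric vector `phi1..phi8`.
#' @export
hu_moments8 <- function(img) {
  check_raster(img, channels = 1L)
  m00 <- sum(img)
  if (m00 <= 0) stop("degenerate moments: image has zero total intensity", call. = FALSE)
  h <- img_height(img); w <- img_width(img)
  x <- 0:(w - 1L)  # column coordinate
  y <- 0:(h - 1L)  # row coordinate
  xb <- sum(img %*% x) / m00
  yb <- sum(y %*% img) / m00
  dx <- x - xb; dy <- y - yb

  mu <- function(p, q) as.numeric((dy^q) %*% img %*% (dx^p))
  eta <- function(p, q) mu(p, q) / m00^(1 + (p + q) / 2)

  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)

  a <- n30 + n12; b <- n21 + n03
  c1 <- n30 - 3 * n12; c2 <- 3 * n21 - n03
  phi <- c(
    n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    c1^2 + c2^2,
    a^2 + b^2,
    c1 * a * (a^2 - 3 * b^2) + c2 * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    c2 * a * (a^2 - 3 * b^2) - c1 * b * (3 * a^2 - b^2),
    2 * n11 * (a^2 - b^2) - 2 * (n20 - n02) * a * b
  )
  names(phi) <- paste0("phi", 1:8)
  phi
}
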
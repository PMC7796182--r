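# Multi-scale, multi-orientation Gabor filter bank features.

#' Complex Gabor kernel (even and odd parts)
#'
#' Builds the quadrature pair of a Gabor filter with carrier wavelength
#' `lambda` (pixels) and orientation `theta` (radians, direction of the
#' carrier wave). The Gaussian envelope sigma follows from a 1-octave
#' half-response spatial-frequency bandwidth; `gamma` is the envelope
#' aspect ratio.
#'
#' @param lambda Carrier wavelength in pixels.
#' @param theta Orientation in radians.
#' @param bandwidth Spatial-frequency bandwidth in octaves (default 1).
#' @param gamma Envelope aspect ratio (default 0.5).
#' @return List with square matrices `even` (cosine) and `odd` (sine).
#' @export
gabor_kernel <- function(lambda, theta, bandwidth = 1, gamma = 0.5) {
  sigma <- lambda / pi * sqrt(log(2) / 2) * (2^bandwidth + 1) / (2^bandwidth - 1)
  half <- ceiling(3 * sigma)
  g <- seq(-half, half)
  x <- matrix(g, 2 * half + 1, 2 * half + 1, byrow = TRUE)
  y <- matrix(g, 2 * half + 1, 2 * half + 1)
  xp <- x * cos(theta) + y * sin(theta)
  yp <- -x * sin(theta) + y * cos(theta)
  env <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2))
  list(even = env * cos(2 * pi * xp / lambda),
       odd  = env * sin(2 * pi * xp / lambda))
}

#' Gabor filter-bank texture features
#'
#' Filters a grayscale image with a bank of 5 scales x 8 orientations
#' (40 filters), takes the magnitude of the quadrature response, splits
#' each magnitude image into a 3x3 grid of sub-blocks, and pools the mean
#' magnitude per sub-block: 5 x 8 x 3 x 3 = 360 values, ordered
#' scale-major, then orientation, then row-major sub-blocks.
#'
#' Default wavelengths form a geometric progression 4, 4*sqrt(2), 8,
#' 8*sqrt(2), 16 pixels; orientations are k*pi/8, k = 0..7.
#'
#' @param img Grayscale matrix.
#' @param lambdas Carrier wavelengths (pixels), one per scale.
#' @param n_theta Number of orientations.
#' @return Numeric vector of length `length(lambdas) * n_theta * 9`.
#' @export
gabor_features <- function(img,
                           lambdas = 4 * 2^(seq(0, 2, by = 0.5)),
                           n_theta = 8L) {
  check_raster(img, channels = 1L)
  h <- img_height(img); w <- img_width(img)
  x <- EBImage::Image(img / 255)
  thetas <- (seq_len(n_theta) - 1L) * pi / n_theta
  rb <- round(h * (0:3) / 3); cb <- round(w * (0:3) / 3)
  out <- numeric(length(lambdas) * n_theta * 9L)
  pos <- 1L
  for (lam in lambdas) {
    for (th in thetas) {
      k <- gabor_kernel(lam, th)
      re <- as.array(EBImage::filter2(x, k$even))
      im <- as.array(EBImage::filter2(x, k$odd))
      mag <- sqrt(re^2 + im^2)
      for (i in 1:3) {
        for (j in 1:3) {
          out[pos] <- mean(mag[(rb[i] + 1L):rb[i + 1L], (cb[j] + 1L):cb[j + 1L]])
          pos <- pos + 1L
        }
      }
    }
  }
  out
}
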
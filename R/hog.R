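# Histogram of oriented gradients over a square cell grid.

#' Histogram of oriented gradients
#'
#' Divides a square grayscale image into `cell x cell` cells, accumulates
#' a 9-bin unsigned orientation histogram per cell (gradients from
#' `[-1, 0, 1]` derivative kernels with edge replication, magnitude-
#' weighted votes over `[0, 180)` degrees), groups each 2x2 quad of
#' adjacent cells into a block (stride one cell, 4 x 9 = 36 values per
#' block), and L2-Hys-normalizes each block. A 256x256 image with 64-pixel
#' cells yields (256/64 - 1)^2 x 36 = 324 dimensions.
#'
#' @param img Grayscale `S x S` matrix, `S` divisible by `cell`.
#' @param cell Cell side in pixels (must not exceed `S`).
#' @param nbins Number of unsigned orientation bins (default 9).
#' @return Numeric vector of length `(S/cell - 1)^2 * 4 * nbins`, blocks
#'   in row-major order, cells row-major within each block.
#' @export
hog_features <- function(img, cell = 64L, nbins = 9L) {
  check_raster(img, channels = 1L)
  s <- img_height(img)
  if (img_width(img) != s) stop("image must be square", call. = FALSE)
  cell <- as.integer(cell)
  if (cell > s) stop("cell size exceeds image side", call. = FALSE)
  if (s %% cell != 0L) stop("image side must be divisible by cell size", call. = FALSE)
  ncell <- s %/% cell
  if (ncell < 2L) stop("need at least a 2x2 cell grid to form blocks", call. = FALSE)

  # Central differences with replicated edges.
  gx <- img[, c(2:s, s)] - img[, c(1L, 1:(s - 1L))]
  gy <- img[c(2:s, s), ] - img[c(1L, 1:(s - 1L)), ]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% pi                       # unsigned, [0, pi)
  bin <- pmin(floor(ang / (pi / nbins)), nbins - 1L)

  rows <- (row(img) - 1L) %/% cell
  cols <- (col(img) - 1L) %/% cell
  cell_idx <- rows * ncell + cols                  # row-major, 0-based
  grp <- cell_idx * nbins + bin + 1L
  nh <- ncell * ncell * nbins
  hist <- numeric(nh)
  sums <- rowsum(as.vector(mag), group = as.vector(grp))
  hist[as.integer(rownames(sums))] <- sums
  ch <- matrix(hist, nrow = nbins)                 # nbins x ncells

  nb <- ncell - 1L
  out <- numeric(nb * nb * 4L * nbins)
  eps <- 1e-5
  pos <- 1L
  for (bi in 0:(nb - 1L)) {
    for (bj in 0:(nb - 1L)) {
      cells <- c(bi * ncell + bj, bi * ncell + bj + 1L,
                 (bi + 1L) * ncell + bj, (bi + 1L) * ncell + bj + 1L) + 1L
      v <- as.vector(ch[, cells])
      n2 <- sum(v^2)
      if (n2 > 0) {
        v <- v / sqrt(n2 + eps^2)
        v <- pmin(v, 0.2)                          # Hys clipping
        n2 <- sum(v^2)
        if (n2 > 0) v <- v / sqrt(n2 + eps^2)
      }
      out[pos:(pos + 4L * nbins - 1L)] <- v
      pos <- pos + 4L * nbins
    }
  }
  out
}
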
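# Rotation-invariant local binary patterns over the 3x3 neighborhood.

# Circular left-rotation of an 8-bit code by k positions.
rot8 <- function(p, k) {
  k <- k %% 8L
  bitwAnd(bitwOr(bitwShiftL(p, k), bitwShiftR(p, 8L - k)), 255L)
}

popcount8 <- function(p) {
  n <- integer(length(p))
  for (b in 0:7) n <- n + bitwAnd(bitwShiftR(p, b), 1L)
  n
}

#' Rotation-invariant LBP code
#'
#' Maps an 8-bit neighborhood code to the minimum over its eight circular
#' bit-rotations, so that rotating the neighborhood (and hence the leaf)
#' leaves the code unchanged. For example, the pattern with decimal value
#' 125 and rotations 250, 245, 235, 215, 175, 95, 190 maps to 95.
#'
#' @param pattern Integer vector of codes in `0..255`.
#' @return Integer vector of minimal-rotation codes.
#' @examples
#' rotlbp_code(125L)  # 95
#' @export
rotlbp_code <- function(pattern) {
  pattern <- as.integer(pattern)
  if (any(pattern < 0L | pattern > 255L)) stop("pattern must be in 0..255", call. = FALSE)
  m <- pattern
  for (k in 1:7) m <- pmin(m, rot8(pattern, k))
  m
}

#' Uniform-pattern bin index (riu2)
#'
#' Maps an 8-bit code to one of 10 rotation-invariant bins: patterns with
#' at most two circular 0/1 transitions ("uniform") are binned by their
#' number of set bits (0..8); all other patterns share bin 9. This is the
#' binning that yields 10 histogram entries per cell.
#'
#' @param pattern Integer vector of codes in `0..255`.
#' @return Integer bin indices in `0..9`.
#' @export
riu2_bin <- function(pattern) {
  pattern <- as.integer(pattern)
  if (any(pattern < 0L | pattern > 255L)) stop("pattern must be in 0..255", call. = FALSE)
  trans <- popcount8(bitwXor(pattern, rot8(pattern, 1L)))
  ifelse(trans <= 2L, popcount8(pattern), 9L)
}

#' Rotation-invariant LBP cell histograms
#'
#' Computes the 8-bit LBP code of every interior pixel from its 3x3
#' neighborhood (clockwise from the top-left neighbor; a bit is set when
#' the neighbor is >= the center, so flat regions are deterministic),
#' maps codes to the 10 riu2 bins, and histograms them per `cell x cell`
#' cell. On a 256x256 image with 64-pixel cells this gives the
#' 4 x 4 x 10 = 160-dimensional descriptor.
#'
#' @param img Grayscale `S x S` matrix, `S` divisible by `cell`.
#' @param cell Cell side in pixels.
#' @param normalize If `TRUE` (default) each cell histogram is scaled to
#'   sum to 1.
#' @return Numeric vector of length `(S/cell)^2 * 10`, cells in row-major
#'   order, 10 bins per cell.
#' @export
rotlbp_features <- function(img, cell = 64L, normalize = TRUE) {
  check_raster(img, channels = 1L)
  s <- img_height(img)
  if (img_width(img) != s) stop("image must be square", call. = FALSE)
  cell <- as.integer(cell)
  if (cell > s) stop("cell size exceeds image side", call. = FALSE)
  if (s %% cell != 0L) stop("image side must be divisible by cell size", call. = FALSE)
  if (s < 3L) stop("image too small for a 3x3 neighborhood", call. = FALSE)

  ri <- 2:(s - 1L); ci <- 2:(s - 1L)
  ctr <- img[ri, ci]
  # Neighbor offsets clockwise from top-left; first neighbor is the MSB.
  offs <- list(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, 1L),
               c(1L, 1L), c(1L, 0L), c(1L, -1L), c(0L, -1L))
  code <- matrix(0L, length(ri), length(ci))
  for (k in seq_along(offs)) {
    nb <- img[ri + offs[[k]][1], ci + offs[[k]][2]]
    code <- code + bitwShiftL(as.integer(nb >= ctr), 8L - k)
  }
  bins <- matrix(.lbp_env$riu2_table[code + 1L], nrow(code), ncol(code))

  ncell <- s %/% cell
  # Cell index of each interior pixel (row-major cells, 0-based).
  cr <- (ri - 1L) %/% cell
  cc <- (ci - 1L) %/% cell
  cell_idx <- outer(cr, cc, function(a, b) a * ncell + b)
  grp <- cell_idx * 10L + bins + 1L
  h <- numeric(ncell * ncell * 10L)
  tab <- tabulate(grp, nbins = length(h))
  h <- as.numeric(tab)
  if (normalize) {
    hm <- matrix(h, nrow = 10L)
    tot <- colSums(hm)
    tot[tot == 0] <- 1
    h <- as.vector(sweep(hm, 2L, tot, "/"))
  }
  h
}

# Precomputed riu2 lookup table for codes 0..255.
.lbp_env <- new.env(parent = emptyenv())

.onLoad <- function(libname, pkgname) {
  .lbp_env$riu2_table <- riu2_bin(0:255)
}
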
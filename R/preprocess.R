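# Image preprocessing: size normalization, grayscale and CIELAB conversion.

# Bilinear resize via EBImage; handles the row-major <-> x-major transpose.
resize_raster <- function(img, h, w) {
  if (is_gray(img)) {
    e <- EBImage::Image(t(img) / 255)
    out <- EBImage::resize(e, w = w, h = h, filter = "bilinear")
    t(as.array(out)) * 255
  } else {
    e <- EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = "Color")
    out <- EBImage::resize(e, w = w, h = h, filter = "bilinear")
    aperm(as.array(out), c(2L, 1L, 3L)) * 255
  }
}

#' Aspect-preserving size normalization with zero padding
#'
#' Scales an image uniformly so its longer side equals `target_side`
#' (bilinear interpolation, no anisotropic distortion -- leaf shape is
#' preserved), places the scaled content on a square zero canvas, and
#' returns the `target_side x target_side` result. The blank region is
#' filled with exact zeros in every channel, matching the convention used
#' to build leaf sample sets on black backgrounds.
#'
#' @param img Gray matrix or `H x W x 3` array, values in `[0, 255]`.
#' @param target_side Side length of the square output canvas (pixels).
#' @param anchor `"topleft"` (default) or `"center"`: where the scaled
#'   content sits on the canvas.
#' @return Raster of size `target_side x target_side` (same channel count).
#' @examples
#' leaf <- matrix(200, 100, 50)
#' out <- normalize_size(leaf, 256)
#' dim(out)          # 256 x 256
#' sum(out[, 129:256]) # padded region is exactly 0
#' @export
normalize_size <- function(img, target_side = 256L, anchor = c("topleft", "center")) {
  check_raster(img)
  anchor <- match.arg(anchor)
  target_side <- as.integer(target_side)
  if (target_side < 1L) stop("target_side must be >= 1", call. = FALSE)
  h <- img_height(img); w <- img_width(img)
  if (h == target_side && w == target_side) return(img)
  s <- target_side / max(h, w)
  nh <- max(1L, as.integer(round(s * h)))
  nw <- max(1L, as.integer(round(s * w)))
  content <- clamp(resize_raster(img, nh, nw), 0, 255)
  r0 <- if (anchor == "center") (target_side - nh) %/% 2L else 0L
  c0 <- if (anchor == "center") (target_side - nw) %/% 2L else 0L
  if (is_gray(img)) {
    canvas <- matrix(0, target_side, target_side)
    canvas[r0 + seq_len(nh), c0 + seq_len(nw)] <- content
  } else {
    canvas <- array(0, c(target_side, target_side, 3L))
    canvas[r0 + seq_len(nh), c0 + seq_len(nw), ] <- content
  }
  canvas
}

#' Convert an RGB raster to grayscale
#'
#' Luminance-weighted combination with Rec. 601 weights
#' (0.299 R + 0.587 G + 0.114 B). Grayscale input is returned unchanged.
#'
#' @param img Raster with values in `[0, 255]`.
#' @return `H x W` matrix in `[0, 255]`.
#' @export
to_gray <- function(img) {
  check_raster(img)
  if (is_gray(img)) return(img)
  img[, , 1] * 0.299 + img[, , 2] * 0.587 + img[, , 3] * 0.114
}

#' Convert an RGB raster to CIE L*a*b*
#'
#' Assumes sRGB input under the D65 white point. Vegetation pixels
#' (saturated greens) map to strongly negative `a`; neutral grays map to
#' `a` and `b` near zero, which is what the field segmentation exploits.
#'
#' @param img `H x W x 3` array, values in `[0, 255]`.
#' @return Object of class `lab_image`: list with `H x W` matrices `L`
#'   (lightness, 0--100), `a` (green--red) and `b` (blue--yellow).
#' @export
rgb_to_lab <- function(img) {
  check_raster(img, channels = 3L)
  h <- img_height(img); w <- img_width(img)
  m <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]), as.vector(img[, , 3]))
  lab <- farver::convert_colour(m, from = "rgb", to = "lab")
  structure(
    list(L = matrix(lab[, 1], h, w),
         a = matrix(lab[, 2], h, w),
         b = matrix(lab[, 3], h, w)),
    class = "lab_image")
}

#' @export
print.lab_image <- function(x, ...) {
  cat(sprintf("CIELAB image %d x %d (L in [%.1f, %.1f], a in [%.1f, %.1f])\n",
              nrow(x$L), ncol(x$L), min(x$L), max(x$L), min(x$a), max(x$a)))
  invisible(x)
}
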
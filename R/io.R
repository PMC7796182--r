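#' Read a raster image
#'
#' Loads a PNG, JPEG, TIFF or BMP file into the package's raster
#' representation: a numeric `H x W` matrix (grayscale) or `H x W x 3`
#' array (RGB), with channel values on the 8-bit scale `[0, 255]` and
#' row-major, 0-based pixel coordinates at the API surface.
#'
#' PNG files are read with \pkg{png}; all other formats go through
#' \pkg{EBImage}. An alpha channel, if present, is dropped.
#'
#' @param path Path to an image file.
#' @return A numeric matrix or `H x W x 3` array with values in `[0, 255]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else {
    e <- EBImage::readImage(path)
    px <- as.array(e)
    # EBImage stores x (width) first; transpose to row-major H x W.
    px <- if (length(dim(px)) == 2L) t(px) else aperm(px, c(2L, 1L, 3L))
  }
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE] else px <- px[, , 1L]
  }
  px * 255
}

#' Write a raster image as PNG
#'
#' @param img Raster matrix or `H x W x 3` array, values in `[0, 255]`.
#' @param path Output path (PNG).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  check_raster(img)
  png::writePNG(clamp(img / 255, 0, 1), path)
  invisible(path)
}
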
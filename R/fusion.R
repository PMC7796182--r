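# Feature fusion: strategy parsing, per-descriptor extraction, concatenation.

DESCRIPTOR_NAMES <- c("HOG", "ROTLBP", "GABOR", "GLCM", "GGCM", "HU")

#' Feature extraction specification
#'
#' A `feature_spec` records which descriptors are fused, in which order,
#' and with which parameters, so that the exact same extraction is applied
#' to training leaves, validation leaves, and field regions. Strategies
#' are written as `"+"`-separated descriptor names, e.g. `"GGCM+RotLBP"`
#' (case-insensitive); concatenation follows the order named.
#'
#' @param strategy Strategy string, e.g. `"GGCM+RotLBP"` or `"HOG"`.
#' @param hog_cell,lbp_cell Cell sizes (pixels) for HOG and RotLBP.
#' @param glcm_levels Gray levels for the co-occurrence matrix.
#' @param glcm_angle Co-occurrence direction in degrees (0, 45, 90, 135).
#' @param ggcm_gray_levels,ggcm_grad_levels GGCM quantization levels.
#' @param image_side Side of the normalized square input (pixels).
#' @param interpolation Resize interpolation recorded for provenance.
#' @return Object of class `feature_spec`.
#' @examples
#' spec <- feature_spec("GGCM+RotLBP")
#' feature_dim(spec)  # 175
#' @export
feature_spec <- function(strategy,
                         hog_cell = 64L, lbp_cell = 64L,
                         glcm_levels = 64L, glcm_angle = 0,
                         ggcm_gray_levels = 64L, ggcm_grad_levels = 64L,
                         image_side = 256L,
                         interpolation = "bilinear") {
  parts <- toupper(trimws(strsplit(strategy, "+", fixed = TRUE)[[1]]))
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) stop("empty strategy string", call. = FALSE)
  bad <- setdiff(parts, DESCRIPTOR_NAMES)
  if (length(bad) > 0L)
    stop("unknown descriptor(s): ", paste(bad, collapse = ", "), call. = FALSE)
  structure(
    list(descriptors = parts,
         params = list(hog_cell = as.integer(hog_cell),
                       lbp_cell = as.integer(lbp_cell),
                       glcm_levels = as.integer(glcm_levels),
                       glcm_angle = glcm_angle,
                       ggcm_gray_levels = as.integer(ggcm_gray_levels),
                       ggcm_grad_levels = as.integer(ggcm_grad_levels),
                       image_side = as.integer(image_side),
                       interpolation = interpolation)),
    class = "feature_spec")
}

descriptor_dim <- function(name, params) {
  s <- params$image_side
  switch(name,
         HOG = (s %/% params$hog_cell - 1L)^2 * 36L,
         ROTLBP = (s %/% params$lbp_cell)^2 * 10L,
         GABOR = 360L,
         GLCM = 6L,
         GGCM = 15L,
         HU = 8L)
}

#' Total dimension of a fusion strategy
#'
#' Sum of the member descriptor dimensions on the normalized input,
#' e.g. `HOG+Gabor` is 324 + 360 = 684 and `GGCM+RotLBP` is 15 + 160 = 175.
#'
#' @param spec A `feature_spec` (or strategy string).
#' @return Integer dimension.
#' @export
feature_dim <- function(spec) {
  if (is.character(spec)) spec <- feature_spec(spec)
  as.integer(sum(vapply(spec$descriptors, descriptor_dim, numeric(1),
                        params = spec$params)))
}

#' @export
print.feature_spec <- function(x, ...) {
  cat(sprintf("feature_spec: %s (%d dims on %dx%d input)\n",
              paste(x$descriptors, collapse = "+"), feature_dim(x),
              x$params$image_side, x$params$image_side))
  invisible(x)
}

#' Concatenate feature vectors
#'
#' Fuses per-descriptor vectors by concatenation, preserving member order.
#'
#' @param parts Nonempty list of numeric vectors.
#' @return Single numeric vector whose length is the sum of part lengths.
#' @export
concat_features <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L)
    stop("parts must be a nonempty list of feature vectors", call. = FALSE)
  unlist(parts, use.names = FALSE)
}

#' Extract fused features from one image
#'
#' Applies every descriptor named in the spec to the image (converted to
#' grayscale and size-normalized if needed) and concatenates the results
#' in strategy order.
#'
#' @param img Raster (gray or color, any size).
#' @param spec A `feature_spec` or strategy string.
#' @return Numeric feature vector of length `feature_dim(spec)`.
#' @export
extract_features <- function(img, spec) {
  if (is.character(spec)) spec <- feature_spec(spec)
  p <- spec$params
  g <- to_gray(img)
  if (img_height(g) != p$image_side || img_width(g) != p$image_side)
    g <- normalize_size(g, p$image_side)
  parts <- lapply(spec$descriptors, function(d) {
    switch(d,
           HOG = hog_features(g, cell = p$hog_cell),
           ROTLBP = rotlbp_features(g, cell = p$lbp_cell),
           GABOR = gabor_features(g),
           GLCM = glcm_stats(glcm(g, levels = p$glcm_levels,
                                  offset = glcm_offset(p$glcm_angle))),
           GGCM = ggcm_stats(ggcm(g, gray_levels = p$ggcm_gray_levels,
                                  grad_levels = p$ggcm_grad_levels)),
           HU = hu_moments8(g))
  })
  concat_features(parts)
}

#' Extract fused features for a list of images
#'
#' @param imgs List of rasters.
#' @param spec A `feature_spec` or strategy string.
#' @return Numeric matrix, one row per image.
#' @export
extract_features_batch <- function(imgs, spec) {
  if (is.character(spec)) spec <- feature_spec(spec)
  t(vapply(imgs, extract_features, numeric(feature_dim(spec)), spec = spec))
}

#' Serialize a feature spec to JSON
#'
#' @param spec A `feature_spec`.
#' @param path Optional file to write to.
#' @return JSON string, invisibly if written to file.
#' @export
spec_to_json <- function(spec, path = NULL) {
  js <- jsonlite::toJSON(list(descriptors = spec$descriptors, params = spec$params),
                         auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
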
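# End-to-end field detection: vegetation segmentation, connected
# components, per-region classification, annotation.

#' Segment vegetation by k-means on the CIELAB a channel
#'
#' Converts the scene to CIELAB and clusters the per-pixel `a`
#' (green--red) values with k-means, k = 2 (10 random restarts under the
#' given seed, so the mask is reproducible). The foreground is the
#' cluster with the lower mean `a` -- vegetation is green, hence negative
#' `a`, while soil sits on the positive side. If the lower cluster mean
#' is not actually negative (no vegetation in the scene), or the channel
#' is constant, an all-background mask is returned with attribute
#' `no_vegetation = TRUE` and a warning.
#'
#' @param img `H x W x 3` field scene, values in `[0, 255]`.
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of k-means restarts.
#' @return Logical `H x W` mask (TRUE = vegetation), possibly with
#'   attribute `no_vegetation`.
#' @export
segment_vegetation <- function(img, seed = 1L, nstart = 10L) {
  check_raster(img, channels = 3L)
  a <- rgb_to_lab(img)$a
  h <- nrow(a); w <- ncol(a)
  no_veg <- function(msg) {
    warning(msg, call. = FALSE)
    structure(matrix(FALSE, h, w), no_vegetation = TRUE)
  }
  if (stats::sd(a) == 0) return(no_veg("degenerate a channel: no vegetation found"))
  km <- with_seed(seed,
                  stats::kmeans(as.vector(a), centers = 2L, nstart = nstart,
                                iter.max = 50L))
  fg <- which.min(km$centers)
  if (km$centers[fg] >= 0)
    return(no_veg("no green cluster (lower mean a is non-negative): no vegetation found"))
  matrix(km$cluster == fg, h, w)
}

# Union-find with path compression, used to merge diagonal label contacts.
uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# 8-connected labeling: EBImage::bwlabel (4-connected flood fill) plus a
# union pass over the two diagonal neighbor directions.
label_components8 <- function(mask) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(as.vector(lab))), nrow(mask), ncol(mask))
  nmax <- max(lab)
  if (nmax == 0L) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]      # down-right diagonal
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]      # down-left diagonal
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  pairs <- unique(rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2])))
  parent <- seq_len(nmax)
  if (nrow(pairs) > 0L) {
    for (r in seq_len(nrow(pairs))) {
      ra <- uf_find(parent, pairs[r, 1]); rb <- uf_find(parent, pairs[r, 2])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(seq_len(nmax), function(i) uf_find(parent, i), integer(1))
  dense <- match(root, sort(unique(root)))
  lab[lab > 0L] <- dense[lab[lab > 0L]]
  lab
}

#' Connected-component regions above a minimum area
#'
#' Labels the binary vegetation mask with 8-connectivity, removes
#' components smaller than `min_area` (soil speckle, noise clusters), and
#' reports each surviving region's area and axis-aligned bounding box in
#' 0-based, half-open pixel intervals.
#'
#' @param mask Logical (or 0/1) matrix.
#' @param min_area Minimum component area in pixels; the default keeps
#'   components of at least 0.1 percent of the image.
#' @return List of class `region_map`: `labels` (integer matrix,
#'   0 = background, surviving regions renumbered 1..K) and `regions`
#'   (data.frame: label, area, r0, c0, r1, c1).
#' @export
extract_regions <- function(mask, min_area = NULL) {
  if (!is.matrix(mask)) stop("mask must be a matrix", call. = FALSE)
  mask <- mask != 0
  if (is.null(min_area)) min_area <- ceiling(0.001 * length(mask))
  lab <- label_components8(mask)
  empty <- list(labels = lab,
                regions = data.frame(label = integer(0), area = integer(0),
                                     r0 = integer(0), c0 = integer(0),
                                     r1 = integer(0), c1 = integer(0)))
  class(empty) <- "region_map"
  if (max(lab) == 0L) return(empty)
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(areas >= min_area)
  if (length(keep) == 0L) { empty$labels[] <- 0L; return(empty) }
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  regions <- do.call(rbind, lapply(seq_along(keep), function(k) {
    idx <- which(lab == k, arr.ind = TRUE)
    data.frame(label = k, area = nrow(idx),
               r0 = min(idx[, 1]) - 1L, c0 = min(idx[, 2]) - 1L,
               r1 = max(idx[, 1]), c1 = max(idx[, 2]))
  }))
  structure(list(labels = lab, regions = regions), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d region(s)\n", nrow(x$regions)))
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}

#' Classify segmented regions with a trained leaf model
#'
#' Each region is cropped by its bounding box, pixels outside the
#' connected component are zeroed (matching the zero-padded leaf training
#' convention), the crop is size-normalized, featurized with the model's
#' feature spec, projected and scaled with the model's PCA and scaler,
#' and classified. Regions too small for the descriptors are skipped with
#' a warning.
#'
#' @param img The original `H x W x 3` scene.
#' @param regions A `region_map` from [extract_regions()].
#' @param model A `weed_model` bundle carrying a `feature_spec`.
#' @param min_side Minimum region box side (pixels) to attempt
#'   classification.
#' @return data.frame of detections: class (`"corn"`/`"weed"`), score
#'   (signed decision value), r0, c0, r1, c1 (half-open box, equal to the
#'   region box), area, label.
#' @export
classify_regions <- function(img, regions, model, min_side = 8L) {
  check_raster(img, channels = 3L)
  if (!inherits(regions, "region_map")) stop("regions must be a region_map", call. = FALSE)
  if (is.null(model$spec)) stop("model bundle has no feature_spec", call. = FALSE)
  out <- list()
  for (k in seq_len(nrow(regions$regions))) {
    reg <- regions$regions[k, ]
    if ((reg$r1 - reg$r0) < min_side || (reg$c1 - reg$c0) < min_side) {
      warning(sprintf("region %d too small to classify; skipped", reg$label),
              call. = FALSE)
      next
    }
    rows <- (reg$r0 + 1L):reg$r1
    cols <- (reg$c0 + 1L):reg$c1
    crop <- img[rows, cols, , drop = FALSE]
    inside <- regions$labels[rows, cols] == reg$label
    crop[!array(inside, dim(crop))] <- 0
    res <- classify_image(model, normalize_size(crop, model$spec$params$image_side))
    out[[length(out) + 1L]] <- data.frame(
      class = res$class, score = res$score,
      r0 = reg$r0, c0 = reg$c0, r1 = reg$r1, c1 = reg$c1,
      area = reg$area, label = reg$label)
  }
  if (length(out) == 0L)
    return(data.frame(class = character(0), score = numeric(0),
                      r0 = integer(0), c0 = integer(0),
                      r1 = integer(0), c1 = integer(0),
                      area = integer(0), label = integer(0)))
  do.call(rbind, out)
}

#' Annotate detections on a scene
#'
#' Draws rectangle outlines over a copy of the image: yellow
#' (255, 255, 0) for corn, red (255, 0, 0) for weeds. Boxes are drawn in
#' detection order, later boxes over earlier ones.
#'
#' @param img `H x W x 3` scene.
#' @param detections Detection data.frame from [classify_regions()].
#' @param thickness Outline thickness in pixels (default 2, drawn inward).
#' @return Annotated copy of `img`.
#' @export
annotate <- function(img, detections, thickness = 2L) {
  check_raster(img, channels = 3L)
  out <- img
  for (k in seq_len(nrow(detections))) {
    d <- detections[k, ]
    col <- if (d$class == "corn") c(255, 255, 0) else c(255, 0, 0)
    rows <- (d$r0 + 1L):d$r1
    cols <- (d$c0 + 1L):d$c1
    t_ <- min(thickness, length(rows), length(cols))
    band_r <- unique(c(rows[seq_len(t_)], rev(rows)[seq_len(t_)]))
    band_c <- unique(c(cols[seq_len(t_)], rev(cols)[seq_len(t_)]))
    for (ch in 1:3) {
      out[band_r, cols, ch] <- col[ch]
      out[rows, band_c, ch] <- col[ch]
    }
  }
  out
}

#' Detect corn seedlings and weeds in a field scene
#'
#' The full pipeline: CIELAB conversion and channel-a k-means
#' segmentation, small-region removal by connected-component analysis,
#' per-region feature extraction and SVM classification, and annotation
#' (yellow = corn, red = weed).
#'
#' @param img `H x W x 3` field scene, values in `[0, 255]`.
#' @param model A trained `weed_model` bundle.
#' @param min_area Minimum component area (pixels); default 0.1 percent
#'   of the image.
#' @param seed Seed for the segmentation k-means.
#' @return List of class `weed_detection`: `detections` (data.frame),
#'   `mask`, `regions` (a `region_map`), `annotated` (raster).
#' @export
detect_weeds <- function(img, model, min_area = NULL, seed = 1L) {
  mask <- segment_vegetation(img, seed = seed)
  regions <- extract_regions(mask, min_area = min_area)
  detections <- classify_regions(img, regions, model)
  structure(list(detections = detections, mask = mask, regions = regions,
                 annotated = annotate(img, detections)),
            class = "weed_detection")
}

#' @export
print.weed_detection <- function(x, ...) {
  n <- nrow(x$detections)
  cat(sprintf("weed_detection: %d region(s) -- %d corn, %d weed\n", n,
              sum(x$detections$class == "corn"), sum(x$detections$class == "weed")))
  if (n > 0) print(x$detections[, c("class", "score", "r0", "c0", "r1", "c1", "area")])
  invisible(x)
}

#' Write detections to JSON
#'
#' @param detection A `weed_detection` or detection data.frame.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
detections_to_json <- function(detection, path) {
  det <- if (inherits(detection, "weed_detection")) detection$detections else detection
  jsonlite::write_json(det[, c("class", "score", "r0", "c0", "r1", "c1", "area")],
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
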
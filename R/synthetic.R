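# Deterministic synthetic leaf and field-scene generator with ground truth.
#
# The generator encodes the cues the descriptors measure: corn blades are
# broad, elongated, smoothly shaded with regular parallel vein striping
# (a mix of regular and random texture over a large area); weed blades
# are thin, multiple, and carry high-frequency speckle (random texture,
# smaller area). Backgrounds are exact zeros, matching the zero-padded
# leaf sample convention, so field-region crops and training leaves share
# one distribution.

# Class parameter ranges at the 256-pixel reference scale. At
# texture_contrast = 1 each class samples from its own ranges; at 0 both
# sample from the midpoint ranges (identical distributions, the negative
# control); in between, range endpoints interpolate linearly.
.leaf_ranges <- list(
  corn = list(n_blades = c(1, 1), len = c(170, 230), width = c(55, 85),
              pow = c(0.55, 0.7), stripe_amp = c(0.25, 0.35),
              stripe_period = c(8, 14), speckle_amp = c(0.02, 0.05),
              green = c(140, 165)),
  weed = list(n_blades = c(3, 5), len = c(70, 120), width = c(13, 22),
              pow = c(0.8, 1.0), stripe_amp = c(0.0, 0.05),
              stripe_period = c(8, 14), speckle_amp = c(0.28, 0.40),
              green = c(130, 155))
)

leaf_params <- function(class, texture_contrast = 1) {
  cl <- .leaf_ranges[[class]]
  other <- .leaf_ranges[[setdiff(c("corn", "weed"), class)]]
  t <- clamp(texture_contrast, 0, 1)
  rng <- function(name) {
    mid <- (cl[[name]] + other[[name]]) / 2
    mid + t * (cl[[name]] - mid)
  }
  draw <- function(name) stats::runif(1, rng(name)[1], rng(name)[2])
  nb <- rng("n_blades")
  list(class = class,
       n_blades = max(1L, as.integer(round(stats::runif(1, nb[1], nb[2])))),
       len = draw("len"), width = draw("width"), pow = draw("pow"),
       stripe_amp = draw("stripe_amp"), stripe_period = draw("stripe_period"),
       speckle_amp = draw("speckle_amp"), green = draw("green"))
}

# 3x3 box smoothing with replicated edges (speckle correlation length 1 px).
box3 <- function(m) {
  p <- pad_replicate1(m)
  h <- nrow(m); w <- ncol(m)
  acc <- matrix(0, h, w)
  for (dr in 0:2) for (dc in 0:2) acc <- acc + p[dr + seq_len(h), dc + seq_len(w)]
  acc / 9
}

# Render a leaf at a given canvas side (pixels). Shape parameters are
# defined at the 256-px reference scale and scaled by side/256. Consumes
# RNG; callers wrap in with_seed.
render_leaf <- function(params, side) {
  sc <- side / 256
  len <- params$len * sc; wid <- params$width * sc
  period <- max(2, params$stripe_period * sc)
  cx <- side / 2 + stats::runif(1, -0.05, 0.05) * side
  cy <- side / 2 + stats::runif(1, -0.05, 0.05) * side
  X <- matrix(seq_len(side), side, side, byrow = TRUE)  # column coord
  Y <- matrix(seq_len(side), side, side)                # row coord
  f <- matrix(1, side, side)
  mask <- matrix(FALSE, side, side)
  theta0 <- stats::runif(1, 0, 2 * pi)
  for (b in seq_len(params$n_blades)) {
    th <- theta0 + (b - 1) * 2 * pi / params$n_blades +
      stats::runif(1, -0.25, 0.25)
    blen <- len * stats::runif(1, 0.85, 1)
    bwid <- wid * stats::runif(1, 0.85, 1)
    # Single blades span the center; radiating blades start just short of
    # it so every blade covers the center pixel and the plant stays one
    # connected component.
    back <- if (params$n_blades == 1L) blen / 2 else 0.15 * blen
    ox <- cx - cos(th) * back
    oy <- cy - sin(th) * back
    u <- (X - ox) * cos(th) + (Y - oy) * sin(th)
    v <- -(X - ox) * sin(th) + (Y - oy) * cos(th)
    tt <- u / blen
    half <- bwid / 2 * pmax(0, sin(pi * clamp(tt, 0, 1)))^params$pow
    mb <- tt > 0 & tt < 1 & abs(v) < half
    phase <- stats::runif(1, 0, 2 * pi)
    shade <- 1 + 0.12 * sin(pi * tt[mb] + phase) +
      params$stripe_amp * sin(2 * pi * v[mb] / period + phase)
    f[mb] <- shade
    mask <- mask | mb
  }
  if (params$speckle_amp > 0) {
    spk <- box3(matrix(stats::rnorm(side * side), side, side))
    f[mask] <- f[mask] + params$speckle_amp * spk[mask] * 3
  }
  f <- clamp(f, 0.3, 1.7)
  g0 <- params$green
  img <- array(0, c(side, side, 3L))
  img[, , 1][mask] <- clamp(0.45 * g0 * f[mask], 1, 255)
  img[, , 2][mask] <- clamp(g0 * f[mask], 1, 255)
  img[, , 3][mask] <- clamp(0.35 * g0 * f[mask], 1, 255)
  list(img = img, mask = mask)
}

crop_to_mask <- function(img, mask) {
  idx <- which(mask, arr.ind = TRUE)
  rows <- min(idx[, 1]):max(idx[, 1])
  cols <- min(idx[, 2]):max(idx[, 2])
  list(img = img[rows, cols, , drop = FALSE],
       mask = mask[rows, cols, drop = FALSE])
}

#' Generate a synthetic leaf sample
#'
#' Draws class-specific blade geometry and texture, renders the leaf at a
#' random working scale, crops to the blade's tight bounding box, and
#' size-normalizes onto a square zero canvas -- the same chain a field
#' region goes through at detection time. Deterministic per
#' `(class, seed, texture_contrast)`.
#'
#' @param class `"corn"` or `"weed"`.
#' @param seed Integer seed.
#' @param size Output canvas side (default 256).
#' @param texture_contrast Class-separability dial in `[0, 1]`: at 1 the
#'   classes use their own shape/texture distributions; at 0 both sample
#'   from a common midpoint distribution (negative control).
#' @return `size x size x 3` raster with exactly-zero background.
#' @export
make_leaf <- function(class = c("corn", "weed"), seed = 0L, size = 256L,
                      texture_contrast = 1) {
  class <- match.arg(class)
  with_seed(seed, {
    params <- leaf_params(class, texture_contrast)
    render_side <- as.integer(round(stats::runif(1, 140, 256)))
    r <- render_leaf(params, render_side)
    cr <- crop_to_mask(r$img, r$mask)
    normalize_size(cr$img, size)
  })
}

#' Generate a labeled synthetic leaf dataset
#'
#' Reproducible collection of corn (+1) and weed (-1) leaves with a
#' manifest. Per-leaf seeds are drawn once from the master seed, so the
#' same call yields an identical dataset.
#'
#' @param n_pos,n_neg Number of corn / weed samples.
#' @param seed Master seed.
#' @param size Leaf canvas side.
#' @param texture_contrast Passed to [make_leaf()].
#' @param dir Optional directory: if given, PNGs and `manifest.csv` are
#'   written there.
#' @return List with `images` (list of rasters), `labels` (+1/-1) and
#'   `manifest` (data.frame: file, class, seed).
#' @export
make_dataset <- function(n_pos, n_neg, seed = 0L, size = 256L,
                         texture_contrast = 1, dir = NULL) {
  if (n_pos < 1L || n_neg < 1L) stop("counts must be >= 1", call. = FALSE)
  n <- n_pos + n_neg
  leaf_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  classes <- c(rep("corn", n_pos), rep("weed", n_neg))
  files <- sprintf("leaf_%s_%04d.png", classes, seq_len(n))
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- make_leaf(classes[i], seed = leaf_seeds[i], size = size,
                             texture_contrast = texture_contrast)
  }
  manifest <- data.frame(file = files, class = classes, seed = leaf_seeds)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (i in seq_len(n)) write_image(images[[i]], file.path(dir, files[i]))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images,
       labels = ifelse(classes == "corn", 1L, -1L),
       manifest = manifest)
}

#' Generate leaf features without storing the images
#'
#' Streams [make_leaf()] output straight through [extract_features()],
#' keeping only the feature matrix -- the memory-friendly route for large
#' training sets. Identical seed handling to [make_dataset()], so the
#' feature rows match what extracting from that dataset would give.
#'
#' @inheritParams make_dataset
#' @param spec A `feature_spec` or strategy string.
#' @return List with `X` (features, one row per leaf), `y` (+1/-1) and
#'   `manifest`.
#' @export
make_feature_dataset <- function(n_pos, n_neg, spec, seed = 0L, size = 256L,
                                 texture_contrast = 1) {
  if (is.character(spec)) spec <- feature_spec(spec)
  if (n_pos < 1L || n_neg < 1L) stop("counts must be >= 1", call. = FALSE)
  n <- n_pos + n_neg
  leaf_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  classes <- c(rep("corn", n_pos), rep("weed", n_neg))
  X <- matrix(0, n, feature_dim(spec))
  for (i in seq_len(n)) {
    img <- make_leaf(classes[i], seed = leaf_seeds[i], size = size,
                     texture_contrast = texture_contrast)
    X[i, ] <- extract_features(img, spec)
  }
  list(X = X, y = ifelse(classes == "corn", 1L, -1L),
       manifest = data.frame(class = classes, seed = leaf_seeds))
}

#' Generate a synthetic field scene with ground truth
#'
#' Builds a brown-soil background (multiplicative low-frequency noise,
#' darker clods, pixel noise) and composites non-overlapping corn and
#' weed plants onto it, recording exact bounding boxes and pixel areas.
#' Plants are rendered at scene scale so their texture statistics match
#' what [make_leaf()] produces after crop-and-normalize.
#'
#' @param n_corn,n_weed Number of plants per class.
#' @param size Scene size `c(height, width)` in pixels (default
#'   600 x 1024).
#' @param seed Integer seed; the same seed gives a pixel-identical scene.
#' @param texture_contrast Passed to the leaf renderer.
#' @param plant_side Range of plant render sides in pixels.
#' @param margin Minimum gap between plant boxes (pixels).
#' @param max_tries Placement retries per plant before failing.
#' @return List with `image` (`H x W x 3`), `truth` (data.frame: class,
#'   r0, c0, r1, c1, area -- half-open 0-based boxes) and `mask`
#'   (logical plant mask).
#' @export
make_field_scene <- function(n_corn = 2L, n_weed = 4L, size = c(600L, 1024L),
                             seed = 1L, texture_contrast = 1,
                             plant_side = c(110L, 180L), margin = 8L,
                             max_tries = 200L) {
  h <- as.integer(size[1]); w <- as.integer(size[2])
  if (h < 256L || w < 256L) stop("scene must be at least 256 x 256", call. = FALSE)
  with_seed(seed, {
    # soil background
    base <- c(125, 95, 62)
    coarse <- matrix(stats::rnorm(ceiling(h / 32) * ceiling(w / 32), 1, 0.06),
                     ceiling(h / 32), ceiling(w / 32))
    field <- resize_raster(coarse * 255, h, w) / 255
    scene <- array(0, c(h, w, 3L))
    for (ch in 1:3) scene[, , ch] <- base[ch] * field
    n_clods <- stats::rpois(1, 12)
    if (n_clods > 0) {
      for (k in seq_len(n_clods)) {
        cy <- stats::runif(1, 1, h); cx <- stats::runif(1, 1, w)
        ry <- stats::runif(1, 8, 35); rx <- stats::runif(1, 8, 35)
        dark <- stats::runif(1, 0.72, 0.88)
        rr <- max(1, floor(cy - ry)):min(h, ceiling(cy + ry))
        cc <- max(1, floor(cx - rx)):min(w, ceiling(cx + rx))
        d2 <- outer(((rr - cy) / ry)^2, ((cc - cx) / rx)^2, "+")
        inside <- d2 < 1
        for (ch in 1:3) {
          sub <- scene[rr, cc, ch]
          sub[inside] <- sub[inside] * dark
          scene[rr, cc, ch] <- sub
        }
      }
    }
    scene <- clamp(scene + array(stats::rnorm(h * w * 3, 0, 2.5), c(h, w, 3L)),
                   0, 255)

    classes <- c(rep("corn", n_corn), rep("weed", n_weed))
    plant_mask <- matrix(FALSE, h, w)
    boxes <- matrix(0L, 0L, 4L)  # occupied boxes: r0,c0,r1,c1 (1-based closed)
    truth <- list()
    for (i in seq_along(classes)) {
      params <- leaf_params(classes[i], texture_contrast)
      side <- as.integer(round(stats::runif(1, plant_side[1], plant_side[2])))
      # Guarantee plants sit comfortably above the detector's default
      # small-region threshold (0.1% of the scene): re-render larger if
      # the blade area came out too small.
      area_floor <- ceiling(0.0016 * h * w)
      for (grow in 1:6) {
        r <- render_leaf(params, side)
        cr <- crop_to_mask(r$img, r$mask)
        if (sum(cr$mask) >= area_floor) break
        side <- as.integer(round(side * 1.2))
      }
      ph <- nrow(cr$mask); pw <- ncol(cr$mask)
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        r0 <- sample.int(h - ph + 1L, 1L)
        c0 <- sample.int(w - pw + 1L, 1L)
        cand <- c(r0, c0, r0 + ph - 1L, c0 + pw - 1L)
        clash <- FALSE
        if (nrow(boxes) > 0L) {
          clash <- any(boxes[, 1] <= cand[3] + margin & boxes[, 3] >= cand[1] - margin &
                       boxes[, 2] <= cand[4] + margin & boxes[, 4] >= cand[2] - margin)
        }
        if (!clash) {
          rows <- r0:(r0 + ph - 1L); cols <- c0:(c0 + pw - 1L)
          for (ch in 1:3) {
            sub <- scene[rows, cols, ch]
            sub[cr$mask] <- cr$img[, , ch][cr$mask]
            scene[rows, cols, ch] <- sub
          }
          plant_mask[rows, cols] <- plant_mask[rows, cols] | cr$mask
          boxes <- rbind(boxes, cand)
          truth[[length(truth) + 1L]] <- data.frame(
            class = classes[i],
            r0 = r0 - 1L, c0 = c0 - 1L,
            r1 = r0 + ph - 1L, c1 = c0 + pw - 1L,
            area = sum(cr$mask))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("scene too crowded: could not place all plants", call. = FALSE)
    }
    truth_df <- if (length(truth) > 0) do.call(rbind, truth) else
      data.frame(class = character(0), r0 = integer(0), c0 = integer(0),
                 r1 = integer(0), c1 = integer(0), area = integer(0))
    list(image = scene, truth = truth_df, mask = plant_mask)
  })
}
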
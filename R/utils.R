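# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG state
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so package functions never perturb a user's stream.
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_gray <- function(img) is.matrix(img)

is_color <- function(img) is.array(img) && length(dim(img)) == 3L && dim(img)[3] == 3L

check_raster <- function(img, channels = NULL) {
  if (!(is_gray(img) || is_color(img)))
    stop("expected an H x W matrix (gray) or H x W x 3 array (color)", call. = FALSE)
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L || length(img) == 0L)
    stop("empty image", call. = FALSE)
  if (!is.null(channels)) {
    nc <- if (is_gray(img)) 1L else 3L
    if (!nc %in% channels)
      stop(sprintf("expected a %s-channel image", paste(channels, collapse = " or ")),
           call. = FALSE)
  }
  invisible(img)
}

img_height <- function(img) dim(img)[1]
img_width  <- function(img) dim(img)[2]

# Quantize 8-bit intensities in [0,255] to `levels` integer bins 0..levels-1.
quantize_gray <- function(img, levels) {
  q <- floor(img * levels / 256)
  q[q > levels - 1] <- levels - 1
  q[q < 0] <- 0
  q
}

# Edge-replicated padding by one pixel, used by 3x3 derivative operators.
pad_replicate1 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c(1L, seq_len(h), h), c(1L, seq_len(w), w)]
}
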
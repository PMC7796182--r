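# Independent brute-force oracles. Deliberately naive (double loops,
# bit strings) so they share no code path with the implementation.

oracle_rotations <- function(p) {
  bits <- as.integer(intToBits(p))[8:1]  # MSB first
  vapply(0:7, function(k) {
    rb <- if (k == 0) bits else c(bits[(k + 1):8], bits[1:k])  # rotate left
    sum(rb * 2^(7:0))
  }, numeric(1))
}

oracle_min_rotation <- function(p) min(oracle_rotations(p))

oracle_transition_count <- function(p) {
  bits <- as.integer(intToBits(p))[1:8]
  sum(bits != c(bits[-1], bits[1]))
}

oracle_quantize <- function(v, levels) min(floor(v * levels / 256), levels - 1)

oracle_glcm <- function(img, levels, offset) {
  h <- nrow(img); w <- ncol(img)
  C <- matrix(0, levels, levels)
  n <- 0
  for (r in 1:h) for (c in 1:w) {
    r2 <- r + offset[1]; c2 <- c + offset[2]
    if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w) {
      i <- oracle_quantize(img[r, c], levels)
      j <- oracle_quantize(img[r2, c2], levels)
      C[i + 1, j + 1] <- C[i + 1, j + 1] + 1
      n <- n + 1
    }
  }
  C / n
}

oracle_glcm_stats <- function(P) {
  g <- nrow(P)
  energy <- 0; contrast <- 0; entropy <- 0; idm <- 0
  mu_i <- 0; mu_j <- 0
  for (i in 1:g) for (j in 1:g) {
    p <- P[i, j]
    energy <- energy + p^2
    contrast <- contrast + ((i - 1) - (j - 1))^2 * p
    if (p > 0) entropy <- entropy - p * log(p)
    idm <- idm + p / (1 + ((i - 1) - (j - 1))^2)
    mu_i <- mu_i + (i - 1) * p
    mu_j <- mu_j + (j - 1) * p
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 1:g) for (j in 1:g) {
    p <- P[i, j]
    v_i <- v_i + ((i - 1) - mu_i)^2 * p
    v_j <- v_j + ((j - 1) - mu_j)^2 * p
    cov <- cov + ((i - 1) - mu_i) * ((j - 1) - mu_j) * p
  }
  correlation <- if (v_i > 0 && v_j > 0) cov / sqrt(v_i * v_j) else 0
  ps <- numeric(2 * g - 1)
  for (i in 1:g) for (j in 1:g) ps[i + j - 1] <- ps[i + j - 1] + P[i, j]
  sum_entropy <- 0
  for (k in seq_along(ps)) if (ps[k] > 0) sum_entropy <- sum_entropy - ps[k] * log(ps[k])
  c(energy = energy, contrast = contrast, correlation = correlation,
    sum_entropy = sum_entropy, entropy = entropy, idm = idm)
}

# Sobel magnitude with edge replication, pixel by pixel.
oracle_sobel <- function(img) {
  h <- nrow(img); w <- ncol(img)
  at <- function(r, c) img[min(max(r, 1), h), min(max(c, 1), w)]
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    gx <- (at(r - 1, c + 1) + 2 * at(r, c + 1) + at(r + 1, c + 1)) -
          (at(r - 1, c - 1) + 2 * at(r, c - 1) + at(r + 1, c - 1))
    gy <- (at(r + 1, c - 1) + 2 * at(r + 1, c) + at(r + 1, c + 1)) -
          (at(r - 1, c - 1) + 2 * at(r - 1, c) + at(r - 1, c + 1))
    out[r, c] <- sqrt(gx^2 + gy^2)
  }
  out
}

oracle_ggcm_counts <- function(img, gray_levels, grad_levels) {
  grad <- oracle_sobel(img)
  gmax <- max(grad)
  C <- matrix(0, gray_levels, grad_levels)
  for (r in 1:nrow(img)) for (c in 1:ncol(img)) {
    i <- oracle_quantize(img[r, c], gray_levels)
    j <- if (gmax > 0) min(floor(grad[r, c] / gmax * grad_levels), grad_levels - 1) else 0
    C[i + 1, j + 1] <- C[i + 1, j + 1] + 1
  }
  C
}

oracle_ggcm_stats <- function(C) {
  n <- sum(C)
  P <- C / n
  gg <- nrow(C); gs <- ncol(C)
  t1 <- 0; t2 <- 0
  for (i in 1:gg) for (j in 1:gs) {
    t1 <- t1 + C[i, j] / j^2
    t2 <- t2 + C[i, j] * j^2
  }
  t1 <- t1 / n; t2 <- t2 / n
  t3 <- sum(sapply(1:gg, function(i) sum(C[i, ])^2)) / n
  t4 <- sum(sapply(1:gs, function(j) sum(C[, j])^2)) / n
  t5 <- sum(P^2)
  p_i <- rowSums(P); p_j <- colSums(P)
  t6 <- sum((1:gg) * p_i); t7 <- sum((1:gs) * p_j)
  t8 <- sqrt(sum(((1:gg) - t6)^2 * p_i))
  t9 <- sqrt(sum(((1:gs) - t7)^2 * p_j))
  t10 <- 0
  for (i in 1:gg) for (j in 1:gs) t10 <- t10 + (i - t6) * (j - t7) * P[i, j]
  ent <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  t11 <- ent(p_i); t12 <- ent(p_j); t13 <- ent(P)
  t14 <- 0; t15 <- 0
  for (i in 1:gg) for (j in 1:gs) {
    t14 <- t14 + (i - j)^2 * P[i, j]
    t15 <- t15 + P[i, j] / (1 + (i - j)^2)
  }
  c(t1, t2, t3, t4, t5, t6, t7, t8, t9, t10, t11, t12, t13, t14, t15)
}

# Raw image moment by explicit double loop (x = column, y = row, 0-based).
oracle_moment <- function(img, p, q, cx = 0, cy = 0) {
  out <- 0
  for (r in 1:nrow(img)) for (c in 1:ncol(img)) {
    out <- out + ((c - 1) - cx)^p * ((r - 1) - cy)^q * img[r, c]
  }
  out
}

oracle_hu <- function(img) {
  m00 <- oracle_moment(img, 0, 0)
  cx <- oracle_moment(img, 1, 0) / m00
  cy <- oracle_moment(img, 0, 1) / m00
  eta <- function(p, q) oracle_moment(img, p, q, cx, cy) / m00^(1 + (p + q) / 2)
  n20 <- eta(2, 0); n02 <- eta(0, 2); n11 <- eta(1, 1)
  n30 <- eta(3, 0); n03 <- eta(0, 3); n21 <- eta(2, 1); n12 <- eta(1, 2)
  a <- n30 + n12; b <- n21 + n03
  c(n20 + n02,
    (n20 - n02)^2 + 4 * n11^2,
    (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    a^2 + b^2,
    (n30 - 3 * n12) * a * (a^2 - 3 * b^2) + (3 * n21 - n03) * b * (3 * a^2 - b^2),
    (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    (3 * n21 - n03) * a * (a^2 - 3 * b^2) - (n30 - 3 * n12) * b * (3 * a^2 - b^2),
    2 * n11 * (a^2 - b^2) - 2 * (n20 - n02) * a * b)
}

# 90-degree counter-clockwise rotation of a matrix image.
rot90m <- function(m) t(m)[ncol(m):1, , drop = FALSE]

# Deterministic pseudo-random test image.
toy_image <- function(h, w, seed = 1, max_val = 255) {
  set.seed(seed)
  matrix(runif(h * w, 0, max_val), h, w)
}
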
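test_that("normalize_size returns square-target inputs unchanged", {
  img <- toy_image(256, 256)
  expect_identical(normalize_size(img, 256), img)
})

test_that("normalize_size scales uniformly and zero-pads the blank region", {
  img <- matrix(200, 100, 50)
  out <- normalize_size(img, 256)
  expect_equal(dim(out), c(256L, 256L))
  # scale 256/100: content becomes 256 x 128, columns 129..256 are blank
  expect_equal(sum(out[, 129:256]), 0)
  expect_true(all(abs(out[, 1:128] - 200) < 1e-6))
  # padded-pixel count matches target^2 - round(s*H)*round(s*W)
  expect_equal(sum(out == 0), 256^2 - 256 * 128)
})

test_that("normalize_size preserves linear ramps in the content region", {
  ramp <- matrix(rep(seq(0, 250, length.out = 60), each = 120), 120, 60)
  out <- normalize_size(ramp, 256)
  # interior of the scaled content is still a (rescaled) linear ramp
  inner <- out[20:230, 10:118]
  expect_gt(cor(as.vector(inner), as.vector(col(inner)))^2, 0.999)
})

test_that("normalize_size is idempotent and supports centered placement", {
  img <- toy_image(90, 40)
  once <- normalize_size(img, 128)
  expect_identical(normalize_size(once, 128), once)
  cen <- normalize_size(img, 128, anchor = "center")
  expect_equal(dim(cen), c(128L, 128L))
  # centered content leaves symmetric zero margins on the short side
  expect_equal(sum(cen[, 1:35]), 0)
  expect_equal(sum(cen[, 93:128]), 0)
})

test_that("normalize_size handles color images and rejects empty input", {
  img <- array(runif(60 * 30 * 3, 0, 255), c(60, 30, 3))
  out <- normalize_size(img, 64)
  expect_equal(dim(out), c(64L, 64L, 3L))
  expect_equal(sum(out[, 33:64, ]), 0)
  expect_error(normalize_size(matrix(numeric(0), 0, 0), 64), "empty")
})

test_that("to_gray uses Rec. 601 luminance weights", {
  black <- array(0, c(4, 4, 3))
  white <- array(255, c(4, 4, 3))
  expect_true(all(to_gray(black) == 0))
  expect_true(all(to_gray(white) == 255))
  red <- array(0, c(4, 4, 3)); red[, , 1] <- 255
  expect_equal(unique(as.vector(to_gray(red))), 0.299 * 255)
  # pixelwise brute-force check on a random image
  img <- array(runif(5 * 5 * 3, 0, 255), c(5, 5, 3))
  g <- to_gray(img)
  for (r in 1:5) for (c in 1:5) {
    expect_equal(g[r, c],
                 0.299 * img[r, c, 1] + 0.587 * img[r, c, 2] + 0.114 * img[r, c, 3])
  }
})

test_that("rgb_to_lab maps black to L=0 and grays to the neutral axis", {
  black <- array(0, c(2, 2, 3))
  expect_true(all(abs(rgb_to_lab(black)$L) < 1e-6))
  # all 256 gray levels stay within 1 unit of a = b = 0
  g <- array(rep(0:255, 3), c(256, 1, 3))
  lab <- rgb_to_lab(g)
  expect_lt(max(abs(lab$a)), 1)
  expect_lt(max(abs(lab$b)), 1)
})

test_that("rgb_to_lab matches the grDevices colorimetric conversion", {
  set.seed(3)
  rgb <- matrix(runif(30, 0, 255), 10, 3)
  img <- array(rgb, c(10, 1, 3))
  lab <- rgb_to_lab(img)
  ref <- grDevices::convertColor(rgb / 255, "sRGB", "Lab")
  expect_true(all(abs(lab$L[, 1] - ref[, 1]) < 1))
  expect_true(all(abs(lab$a[, 1] - ref[, 2]) < 1))
  expect_true(all(abs(lab$b[, 1] - ref[, 3]) < 1))
  # saturated green is strongly negative on the a axis
  green <- array(c(0, 255, 0), c(1, 1, 3))
  expect_lt(rgb_to_lab(green)$a[1, 1], -60)
})
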
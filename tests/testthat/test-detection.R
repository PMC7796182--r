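# A small shared model for region-classification tests.
tiny_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fd <- make_feature_dataset(40, 40, "GGCM+RotLBP", seed = 77)
      pca <- fit_pca(fd$X, 30)
      cache <<- train_svm(apply_pca(pca, fd$X), fd$y,
                          spec = feature_spec("GGCM+RotLBP"), pca = pca)
    }
    cache
  }
})

test_that("vegetation segmentation recovers the planted mask", {
  sc <- make_field_scene(2, 3, size = c(400, 512), seed = 5)
  m1 <- segment_vegetation(sc$image, seed = 1)
  inter <- sum(m1 & sc$mask); uni <- sum(m1 | sc$mask)
  expect_gte(inter / uni, 0.9)
  # determinism under the seed
  expect_identical(m1, segment_vegetation(sc$image, seed = 1))
})

test_that("soil-only and degenerate scenes are flagged as vegetation-free", {
  soil <- make_field_scene(0, 0, size = c(256, 256), seed = 2)$image
  expect_warning(m <- segment_vegetation(soil, seed = 1), "no vegetation")
  expect_true(isTRUE(attr(m, "no_vegetation")))
  expect_false(any(m))
  flat <- array(rep(c(120, 90, 60), each = 256 * 256), c(256, 256, 3))
  expect_warning(m2 <- segment_vegetation(flat, seed = 1), "no vegetation|degenerate")
  expect_false(any(m2))
})

test_that("extract_regions filters small components and reports half-open boxes", {
  mask <- matrix(FALSE, 120, 200)
  mask[2:3, 4:5] <- TRUE                    # area 4 (tiny)
  mask[11:35, 11:30] <- TRUE                # area 500
  mask[61:110, 101:140] <- TRUE             # area 2000
  rg <- extract_regions(mask, min_area = 100)
  expect_equal(nrow(rg$regions), 2L)
  expect_setequal(rg$regions$area, c(500L, 2000L))
  big <- rg$regions[rg$regions$area == 2000, ]
  expect_equal(c(big$r0, big$c0, big$r1, big$c1), c(60, 100, 110, 140))
  # labels contiguous from 1 and consistent with areas
  expect_setequal(setdiff(unique(as.vector(rg$labels)), 0L), rg$regions$label)
})

test_that("empty masks yield zero regions and diagonal contact joins components", {
  expect_equal(nrow(extract_regions(matrix(FALSE, 10, 10), 1)$regions), 0L)
  diag2 <- matrix(FALSE, 10, 10)
  diag2[3, 3] <- TRUE; diag2[4, 4] <- TRUE
  rg <- extract_regions(diag2, min_area = 1)
  expect_equal(nrow(rg$regions), 1L)
  expect_equal(rg$regions$area, 2L)
})

test_that("detections carry the region boxes through unchanged", {
  sc <- make_field_scene(1, 2, size = c(400, 512), seed = 8)
  res <- detect_weeds(sc$image, tiny_model(), seed = 1)
  d <- res$detections
  expect_equal(nrow(d), nrow(res$regions$regions))
  expect_equal(d[, c("r0", "c0", "r1", "c1")],
               res$regions$regions[, c("r0", "c0", "r1", "c1")])
  expect_true(all(d$r1 <= nrow(sc$image) & d$c1 <= ncol(sc$image)))
  expect_true(all(d$class %in% c("corn", "weed")))
})

test_that("classify_regions on an empty region map returns an empty frame", {
  img <- make_field_scene(0, 0, size = c(256, 256), seed = 3)$image
  rg <- extract_regions(matrix(FALSE, 256, 256), 10)
  d <- classify_regions(img, rg, tiny_model())
  expect_equal(nrow(d), 0L)
})

test_that("annotate changes exactly the perimeter band of each box", {
  img <- array(runif(100 * 100 * 3, 0, 200), c(100, 100, 3))
  expect_identical(annotate(img, data.frame()), img)
  det <- data.frame(class = "corn", score = 1,
                    r0 = 10L, c0 = 20L, r1 = 40L, c1 = 60L,
                    area = 100L, label = 1L)
  out <- annotate(img, det, thickness = 2L)
  changed <- which(apply(out != img, c(1, 2), any), arr.ind = TRUE)
  inside_band <- function(r, c) {
    r >= 11 & r <= 40 & c >= 21 & c <= 60 &
      (r <= 12 | r >= 39 | c <= 22 | c >= 59)
  }
  expect_true(all(inside_band(changed[, 1], changed[, 2])))
  # the full band is yellow
  expect_true(all(out[11:12, 21:60, 1] == 255))
  expect_true(all(out[11:12, 21:60, 2] == 255))
  expect_true(all(out[11:12, 21:60, 3] == 0))
  # interior untouched
  expect_identical(out[15:36, 25:56, ], img[15:36, 25:56, ])
})
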
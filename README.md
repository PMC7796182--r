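# weedsight

Recognition and localization of **corn (maize) seedlings versus weeds**
in top-down field images, for precision spraying and precision
fertilization. A sprayer or fertilizer needs per-plant positions: spray
herbicide on the weeds, fertilizer on the crop. `weedsight` provides
the classical-vision pipeline for this task at the 2–5 leaf corn
seedling stage:

1. **Leaf classification.** Six descriptors measure the shape and
   texture cues that distinguish broad, regularly veined corn blades
   from thin, finely textured weed leaves:
   - HOG (histogram of oriented gradients; 324 dims at 64-px cells),
   - rotation-invariant LBP (min-over-rotations codes and 10-bin riu2
     cell histograms; 160 dims),
   - Hu invariant moments φ₁..φ₇ plus the eighth invariant
     φ₈ = 2η₁₁[(η₃₀+η₁₂)² − (η₀₃+η₂₁)²] − 2(η₂₀−η₀₂)(η₃₀+η₁₂)(η₂₁+η₀₃),
   - a 5-scale × 8-orientation Gabor bank, mean magnitude over 3×3
     sub-blocks (360 dims),
   - GLCM with 64 gray levels, P(i,j) = C(i,j)/N at the 0° unit
     displacement, 6 statistics,
   - GGCM (gray level–gradient co-occurrence), 15 statistics.

   Descriptors are fused by concatenation (any `"+"`-strategy such as
   `"GGCM+RotLBP"`, 15 + 160 = 175 dims), reduced by PCA with a stored
   mean and projection, standardized, and classified by an SVM with
   labels corn = +1, weed = −1. Accuracy is
   (TP + TN)/(TP + FP + FN + TN).

2. **Field detection.** Scenes are converted to CIELAB; k-means (k = 2)
   on the *a* (green–red) channel separates vegetation (negative *a*)
   from soil; 8-connected components below a minimum area are removed;
   each surviving region is cropped, zero-masked, size-normalized to
   256×256, and classified; corn is annotated with yellow rectangles,
   weeds with red.

Because no leaf/field image set is distributed, the package ships a
deterministic **synthetic generator** (`make_leaf`, `make_dataset`,
`make_field_scene`) that emulates both sample types with ground truth,
including a `texture_contrast` dial whose zero setting is a negative
control (identical class distributions).

## Worked example

```r
library(weedsight)

spec <- feature_spec("GGCM+RotLBP")
spec
#> feature_spec: GGCM+ROTLBP (175 dims on 256x256 input)

# 300 corn + 300 weed synthetic leaves -> features -> PCA -> 70/30 -> SVM
fd  <- make_feature_dataset(300, 300, spec, seed = 1)
pca <- fit_pca(fd$X, 94)
S   <- apply_pca(pca, fd$X)
idx <- split_dataset(fd$y, 0.7, seed = 0)
model <- train_svm(S[idx$train, ], fd$y[idx$train], spec = spec, pca = pca)
ev <- evaluate(model, S[idx$validation, ], fd$y[idx$validation])
ev$counts
#> TP FP FN TN
#> 90  0  0 90
ev$accuracy
#> [1] 1
```

The confusion counts are over the 90 + 90 held-out leaves (TP: corn
classified as corn; TN: weed as weed). On a synthetic field scene the
end-to-end detector returns one detection per plant with its half-open
bounding box, pixel area, and signed SVM decision score (positive
toward corn):

```r
scene <- make_field_scene(n_corn = 2, n_weed = 4, seed = 11)
res <- detect_weeds(scene$image, model, seed = 1)
res
#> weed_detection: 6 region(s) -- 2 corn, 4 weed
#>   class      score  r0  c0  r1  c1 area
#> 1  weed -1.2769928 238 222 319 302 1495
#> 2  weed -1.1994802   6 254  93 345 1249
#> 3  weed -1.0054238 346 349 424 436 1390
#> 4  corn  0.9071049  68 373 149 466 3772
#> 5  corn  1.3929062 323 487 431 530 3137
#> 6  weed -0.9894229 465 537 554 611 1373
write_image(res$annotated, "scene_annotated.png")
```

A thin command-line front end (`inst/exec/weedsight`) wraps the same
functions as `make-data`, `train`, and `detect` subcommands.

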
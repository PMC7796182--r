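Package: weedsight
Title: Weed and Corn Seedling Recognition and Detection by Multi-Feature
    Fusion and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recognition of corn (maize) seedlings versus weeds from leaf
    images, and localization of both in top-down field scenes, for
    precision spraying and fertilization. Implements six leaf descriptors
    (histogram of oriented gradients, rotation-invariant local binary
    patterns, Hu invariant moments with the eighth moment, a 5-scale by
    8-orientation Gabor filter bank, gray-level co-occurrence statistics,
    and gray level-gradient co-occurrence statistics), feature-level
    fusion with principal-component reduction, a support vector machine
    leaf classifier, and an end-to-end field detector based on k-means
    clustering of the CIELAB a channel followed by connected-component
    analysis and per-region classification. A deterministic synthetic
    leaf and field-scene generator with ground truth supports training
    and evaluation without field imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    farver,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
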
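Package: berrybruise
Title: Quantifying Internal Bruising of Blueberries from Sliced-Fruit Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A model-agnostic toolkit for high-throughput assessment of
    internal bruising in blueberry cultivars from plate images of sliced
    fruit. Provides per-berry detection and cross-section/bruise
    segmentation behind a pluggable backend contract (a classical
    image-processing reference backend and a file backend for externally
    produced predictions), pixel-based bruising-ratio computation,
    detection and segmentation evaluation metrics (precision, recall,
    average precision, mAP over IoU thresholds, RMSE/MAE/MAPE), and a
    per-cultivar susceptibility screen (exact 1-D two-means clustering
    with a susceptibility threshold, Welch's t-test, and the
    ratio-vs-firmness regression). A deterministic synthetic plate-image
    generator with exact per-berry ground truth makes every stage testable
    without real imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
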
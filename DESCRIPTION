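Package: lungrpn
Title: Lung Nodule Detection with Fuzzy C-Means Anchor Priors and
    Coordinate Attention
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested toolkit for region-proposal based pulmonary nodule
    detection in CT slices. Provides Hounsfield-unit lung-field
    preprocessing (binarization, border clearing, per-lung morphological
    expansion, windowing, bone removal), anchor-shape priors fitted to
    bounding-box populations by k-means and fuzzy c-means clustering,
    region-proposal-network geometry (anchor grids, IoU, anchor labeling,
    offset encoding, non-maximum suppression), squeeze-and-excitation and
    coordinate-attention feature gating blocks, scaled-down configurable
    backbone classifiers with multi-backbone fusion, detection metrics
    with k-fold cross-validation, and a synthetic CT phantom generator
    with ground-truth nodules so the full pipeline is exercisable without
    external data. Results are tibbles; fitted objects have tidy(),
    glance() and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
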
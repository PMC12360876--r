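Package: usmix
Title: Mixed-Sample Data Augmentation for Ultrasound Lesion Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for expanding small annotated ultrasound lesion
    segmentation datasets with pseudolabeled samples. Implements five
    mixed-sample augmentation operators (PixMix, SegMix2, LesionBlend,
    LesionBlend2, PixMix2) that fuse a labeled image/mask pair with an
    unlabeled image while keeping the segmentation mask unaltered, the
    traditional rotation/translation/Gaussian-noise baselines, a
    subset-then-expand dataset protocol for low-annotation regimes,
    Dice/Jaccard/95th-percentile-Hausdorff evaluation metrics, and a
    seeded speckle-phantom generator so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
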
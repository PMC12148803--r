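Package: symcycle
Title: Unsupervised Lung Tumor Segmentation by Symmetry-Constrained
    Cycle-Consistent Adversarial Translation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trains an unpaired image-to-image translation model that maps
    tumor-bearing lung CT slices to synthetic tumor-free slices, using a
    cycle-consistent adversarial objective augmented with a bilateral
    lung-symmetry discriminator. Tumor masks are then segmented from the
    residual between each slice and its synthetic healthy counterpart via
    Otsu thresholding, median filtering and morphological opening. Includes
    a seeded generator of mirror-symmetric lung CT phantoms for end-to-end
    evaluation, and overlap (Dice, PPV, sensitivity) and surface-distance
    (95th-percentile Hausdorff, average surface distance) metrics. All
    networks and their training loop are implemented natively on BLAS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    png,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
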
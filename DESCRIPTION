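Package: panelmae
Title: Channel-Wise Masked Autoencoder Imputation and Panel Selection for
    Multiplexed Tissue Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Imputes held-out marker channels of multiplexed tissue imaging
    (CyCIF-style) single-cell image stacks with a channel-wise masked
    autoencoder: each 32x32 marker channel becomes one patch of a vision
    transformer grid, a fixed fraction of channels is masked during
    self-supervised training, and the decoder in-paints the missing
    channels. Includes the iterative greedy panel-selection algorithm that
    orders markers by their value for reconstructing the remainder
    (Spearman correlation of per-cell mean intensities), preprocessing of
    core/slide images into aligned single-cell crops (8-bit rescaling,
    core-level QC, histogram matching, moment-based pose alignment,
    core-level k-fold splits), Spearman/SSIM evaluation, a synthetic
    single-cell image generator with known co-expression ground truth, and
    an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
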
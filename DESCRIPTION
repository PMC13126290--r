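Package: ploidyscale
Title: Neuron Size Scaling, Cell-Cycle Deconvolution, and Behavior Analysis for Ploidy Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis chain for diploid-versus-triploid brain
    studies in Xenopus tadpoles: single-neuron 3D morphometry from SWC
    reconstructions with surface-area-to-volume scaling classification,
    flow-cytometry gating with bead-normalized absolute cell counting and
    Dean-Jett-Fox DNA-content cell-cycle deconvolution combined with
    Gaussian-mixture fits of log marker intensities, pERK/ERK ratio-image
    quantification with Huang fuzzy-entropy thresholding, and startle/cruise
    swim-trajectory analysis. Includes seeded synthetic-data generators that
    emulate the statistical structure of each data type for validation and
    parameter-recovery testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    minpack.lm,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    png
Config/testthat/edition: 3
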
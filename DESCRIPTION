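Package: plexus
Title: Quantitative Analysis of Enteric Nervous System Network Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated quantification of enteric nervous system (ENS) wholemount
    networks from confocal z-stacks: pre-filtering and maximum-intensity
    z-projection, trainable (random-forest) pixel segmentation of the neural
    network with an Otsu fallback, skeletonization (2D thinning and 3D ridge
    detection), skeleton-graph construction with junction and branch censuses,
    network density and binned interganglionic-area analysis, structure-tensor
    orientation and coherency, automated soma counting, Welch-t cohort
    statistics and delta-delta-Ct expression analysis. Includes a synthetic
    fluorescence-microscopy generator that renders ganglion/fibre networks with
    exact ground truth, so every stage of the pipeline can be validated and its
    detection power demonstrated without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
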
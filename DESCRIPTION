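Package: aortrack
Title: Longitudinal Quantification of Thoracic Aortic Dilatation from CT Angiography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automatic measurement of thoracic aorta growth between a
    baseline and a follow-up CT angiography scan. Extracts the aortic
    centerline by wave-propagation shortest paths under a Gaussian lumen
    intensity model, fits a deformable Loop-subdivision tube surface to the
    lumen boundary, aligns the follow-up scan by rigid and affine
    mutual-information registration with stochastic gradient ascent, and
    measures maximal cross-sectional diameters (and their changes) at the
    seven standardized thoracic-aorta landmarks. Includes a synthetic
    candy-cane aortic phantom generator with exact ground truth, diameter
    curves, a per-ring dilatation field, and Bland-Altman / intraclass
    correlation agreement statistics for method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
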
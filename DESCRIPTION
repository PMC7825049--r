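Package: diaphanosim
Title: Monte Carlo Simulation and Image Quantification for Digital
    Diaphanoscopy of the Maxillary Sinuses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Weighted-photon Monte Carlo simulation of red (650 nm) and
    near-infrared (850 nm) light transport through a sex-specific
    eight-layer model of the human maxillary sinus (healthy, cystic and
    tumor variants), with detector-plane irradiance scoring; a simulation
    campaign relating detected flux to anatomy and pathology; a synthetic
    camera model rendering transillumination images with configurable
    exposure, gain, bit depth and noise; and diaphanoscopic image
    quantification (transmitted-light percentage over sinus regions of
    interest, pseudo-color intensity segmentation and a left-right
    asymmetry index).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    mgcv,
    optparse,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
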
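Package: cortexsheet
Title: Multiscale Wilson-Cowan Cortical Sheet Model of Focal Seizure Onset
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a two-dimensional sheet of cortical minicolumns, each
    modelled as a Wilson-Cowan excitatory-inhibitory population pair, coupled
    by dense local Gaussian connectivity and remote patchy excitatory
    projections. Provides fixed-step stochastic integration with
    per-macrocolumn shared noise, parameter ramps, pulse and reset stimuli,
    regime classification of the mean-field dynamics (background, bistable,
    oscillatory, upper state), recruitment detection with wavefront-speed
    estimation, microdomain and subcluster placement, stimulation-threshold
    probes, counter-stimulation and microincision experiments, and turn-key
    scenario drivers for the three classes of focal seizure onset mechanism.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
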
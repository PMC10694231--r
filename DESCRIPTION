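Package: wheatcanopy
Title: Wheat Canopy Biophysical Variable Estimation from Proximal Imagery
Version: 0.1.0
Authors@R: person("Canopy", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimation of winter wheat biophysical variables (dry matter,
    leaf area index, nitrogen concentration and nitrogen uptake, plus their
    partitioning among stem, inferior leaves, flag leaf and ear) from nadir
    RGB and six-band multispectral canopy images. Implements a two-stage
    semi-supervised training pipeline in which a first model, trained on
    sparse destructive reference measurements, pseudo-labels the dense
    unlabeled image series and the pseudo-labels are corrected by fitting
    per-microplot growth curves against thermal time before a second model
    is retrained on them. Includes a compact convolutional regression
    network with single- and multi-output (softmax proportion) heads and
    masked, organ-weighted squared-error losses; an engineered-feature
    partial-least-squares baseline with sequential backward feature
    selection under grouped cross-validation; vegetation-index and canopy
    feature extraction (Otsu plant segmentation, 95th-percentile height);
    nitrogen nutrition index computation; and a synthetic field-trial
    generator so the whole pipeline is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
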
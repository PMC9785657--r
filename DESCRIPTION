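Package: ntskill
Title: Autonomous Non-Technical Skill Assessment for Surgical Training
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying non-technical surgical skills and workload in
    minimally invasive surgery (MIS) box training from sensor time series.
    Provides a synthetic cohort generator for SURG-TLX workload questionnaires,
    tool trajectories and three-axis force signals; pooled and paired t-test
    workload statistics; a discriminative correlation-filter instrument tracker
    with channel-reliability weighting and region-of-interest re-selection;
    synchronization and zero-padded assembly of nine-channel multivariate time
    series; a fully convolutional network (conv - batch-norm - ReLU - global
    average pooling - softmax) binary time-series classifier; and leave-one-out
    cross-validated accuracy grids over workload label dimensions and sensor
    channel subsets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
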
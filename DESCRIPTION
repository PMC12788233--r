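Package: ecgrecon
Title: Twelve-Lead ECG Reconstruction from Lead I with Metadata Fusion
    and Monte Carlo Dropout Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the standard 12-lead electrocardiogram from a
    single Lead I recording using a dual-branch neural network that fuses
    the waveform with discretized clinical metadata (frontal QRS and T
    axes, ventricular rate, QRS count, QRS duration).  Provides a
    parametric 12-lead ECG simulator with ground-truth metadata, the full
    preprocessing chain (decimation, windowing, clinical discretization,
    one-hot encoding, record-level splits), a CNN-BiLSTM reconstruction
    model with two baselines (early-fusion backbone and a 1-D U-Net),
    Monte Carlo dropout predictive uncertainty with reliability analysis,
    and an evaluation suite with per-lead and per-segment correlation,
    RMSE, 1-D structural similarity, and paired statistical comparisons
    with Holm correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
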
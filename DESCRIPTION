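Package: wristbp
Title: Cuff-Less Wristwatch Blood Pressure Estimation and Device Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for estimating blood pressure from paired
    ECG and photoplethysmography (PPG) signals recorded by a cuff-less
    wristwatch device, together with the biostatistics needed to validate
    such a device against a manual sphygmomanometer. Includes a synthetic
    ECG/PPG signal simulator with known ground truth, zero-phase Butterworth
    denoising, R-peak detection and beat segmentation, correlation-based
    signal-quality gating, per-beat feature extraction (pulse transit time,
    PPG spectrum, pulse morphology), two-stage outlier screening (univariate
    3-sigma plus autoencoder reconstruction error), a batch-normalized
    fully-connected neural network with cross-validated architecture search,
    per-subject affine calibration of the network read-out, and ESH-style
    validation statistics (sequential-protocol pairing, Bland-Altman limits
    of agreement, accuracy bins, RMSE, paired t-test, and a 2-of-3
    hypertension concordance analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
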
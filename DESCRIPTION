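Package: ecgmend
Title: Denoising, Missing-Segment Reconstruction and Rhythm Classification
    for 12-Lead ECG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A multi-stage pipeline for 12-lead electrocardiogram analysis:
    a transformer-convolutional denoising autoencoder trained with a
    frequency-weighted Huber plus cosine-similarity loss, missing-segment
    reconstruction by either a masked variational autoencoder or an
    ECG-adapted temporal fusion transformer with quantile outputs,
    Pan-Tompkins QRS delineation with morphological feature extraction,
    and a classifier-comparison harness (bootstrap variability, paired
    McNemar tests).  Includes a synthetic 12-lead ECG generator with known
    fiducial annotations, mixed-noise injection and seeded missing-data
    simulation, plus a WFDB format-16 reader/writer and leakage-free
    patient-level data splitting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    jsonlite,
    yaml,
    ranger,
    e1071,
    rpart,
    nnet,
    class,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
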
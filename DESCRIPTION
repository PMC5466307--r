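Package: rtsystole
Title: End-Systole Timing from Real-Time Phase-Contrast MRI and
    Patient-Adapted Cardiac Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the duration of ventricular systole on every heart beat
    from real-time phase-contrast (RTPC) MRI acquisitions that repeat only the
    central k-space line, and fits a per-subject linear model (the
    patient-adapted cardiac model, PACM) predicting end-systole time from
    instantaneous heart rate. Includes a deterministic simulator of RTPC echo
    streams and ECG traces with ground truth, shared-velocity-encoding
    reconstruction of the 1D+t velocity map, SVD-based automatic segmentation
    of the ascending aorta, ECG R-wave refinement and cycle screening,
    iterative-baseline end-systole detection, robust model fitting with a
    residual-SD quality gate, Bland-Altman model comparison, and a bi-phasic
    cine time projection illustrating the impact of end-systole prediction on
    retrospectively gated cine reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
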
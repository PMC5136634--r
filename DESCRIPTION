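Package: gawsense
Title: Frame-Rate Sensitivity Analysis for Glottal Area Waveform Parameters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how objective vocal-fold vibration measures
    extracted from laryngeal high-speed videoendoscopy depend on the camera
    recording frame rate. Generates ground-truth-annotated synthetic glottal
    area waveforms (GAWs) and endoscopy-like frame stacks, segments the
    glottis from image stacks, emulates slower cameras by frame decimation,
    detects oscillation cycles with their phase landmarks, computes twenty
    clinically used GAW parameters (time quotients, amplitude dynamics,
    jitter/shimmer perturbation measures, and spectral noise measures), and
    classifies each parameter's frame-rate stability with a nonparametric
    repeated-measures procedure (Friedman gating, pairwise Wilcoxon
    signed-rank tests with Bonferroni correction, stable-interval merging,
    and a four-group stability taxonomy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    nortest,
    tibble,
    tidyr,
    tiff
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
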
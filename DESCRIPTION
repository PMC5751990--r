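Package: qusrm
Title: Quantitative Ultrasound Response Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for monitoring tumor response to neoadjuvant chemotherapy
    from raw radio-frequency (RF) ultrasound data. Implements reference-phantom
    normalized backscatter spectral analysis (midband fit, spectral slope,
    spectral intercept), spectral-difference attenuation estimation, spherical
    Gaussian scatterer-model fits (average scatterer diameter and acoustic
    concentration), autoregressive scatterer-spacing estimation, parametric-map
    construction, gray-level co-occurrence texture features, multi-feature
    RBF-SVM response classification with balanced subsampling and sequential
    forward selection, gated group statistics, and Kaplan-Meier recurrence-free
    survival analysis. Ships a synthetic RF-phantom and patient-cohort simulator
    with known ground truth so every stage is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    e1071,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
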
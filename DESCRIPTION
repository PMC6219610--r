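Package: ufdhemo
Title: Multi-Parametric Ultrafast Doppler Analysis of Cerebral Hemodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for ultrafast Doppler (UfD)
    functional ultrasound studies of cerebral hemodynamics in cardiac
    arrest and resuscitation models. Generates synthetic ultrafast
    plane-wave IQ data with known hemodynamic ground truth, reconstructs
    images by delay-and-sum beamforming with coherent compounding,
    separates blood echoes from tissue clutter with a spatiotemporal
    singular value decomposition filter, derives power-Doppler and
    relative cerebral blood volume maps, estimates vascular resistivity
    from per-pixel Doppler spectrograms, quantifies regional hyperemia
    with time-normalized areas under the curve, exact Mann-Whitney U
    tests and Cohen's d effect sizes, and assesses cerebral
    autoregulation from standardized blood-volume versus arterial
    pressure point clouds by principal component analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    dplyr,
    tibble,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    readr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
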
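Package: fusulm
Title: Functional Ultrasound and Ultrasound Localization Microscopy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for ultrafast ultrasound neuroimaging of small,
    deep structures such as the trigeminal ganglion. Provides SVD clutter
    filtering of beamformed frame stacks on per-block Casorati matrices,
    Power Doppler image formation, GLM activation mapping against a
    four-half-cosine hemodynamic response function with Bonferroni-corrected
    Z-score maps, region-of-interest extraction and percent blood-volume
    (dBV) quantification, linear mixed-model statistics for evoked responses
    with a signed-square-root transform, and ultrasound localization
    microscopy: microbubble detection, optimal-assignment track linking,
    velocimetry, and super-resolved density and velocity map rendering. A
    seeded synthetic-data generator emulates both acquisition types so the
    whole chain is testable without raw data.
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
    rlang,
    ggplot2,
    generics,
    lme4,
    lmerTest,
    jsonlite,
    yaml,
    tiff,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
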
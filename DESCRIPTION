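Package: enhv
Title: Normative Modeling of Brainstem and Cerebral Volumes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds and applies normative regression models for the expected
    normal healthy volume (ENHV) of the whole brainstem, its subfields
    (medulla, pons, midbrain), and the cerebrum, using intracranial volume,
    age, and sex as predictors. Ships a published coefficient set, the full
    model-building procedure (Pearson screening, sex-by-ICV interaction
    testing, stratified or pooled least squares), ICC-based validation with
    reliability bands, ENHV-adjusted volume statistics for quantifying
    regional atrophy in diffuse axonal injury, a nonparametric group and
    correlation analysis battery, FreeSurfer morphometry table readers, and
    seeded synthetic-cohort generators calibrated to published healthy and
    patient summary statistics.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
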
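Package: wmasym
Title: Lifespan Normative Charts of White Matter Asymmetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building lifespan normative charts of hemispheric
    lateralization in white matter tracts. Computes lateralization indices
    from bilateral tract-feature measures, fits heteroscedastic Gaussian
    location-scale models with fractional-polynomial age smooths selected by
    BIC (with cohort offsets on both the mean and the log standard
    deviation), derives centile charts and rightward-prevalence curves, and
    summarizes lifespan dynamics: median-trajectory derivatives,
    lateralization reversals, epoch slopes of asymmetry magnitude, and
    handedness-stratified Cohen's d profiles. Includes a multi-cohort
    synthetic-data generator with known ground-truth trajectories for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
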
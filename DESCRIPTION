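Package: bioagefmd
Title: Biological Age, Gompertz Mortality Models and Fasting-Mimicking Diet
    Lifecourse Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates Klemera-Doubal (KDM) biological age from a panel of
    seven clinical chemistry biomarkers, fits Gompertz proportional-hazard
    mortality models to derive median remaining life expectancy and 20-year
    (cause-specific) mortality risk, and simulates the lifecourse effect of
    annual fasting-mimicking diet (FMD) cycles on biological age using
    published response-surface coefficients with survey-weighted Monte Carlo
    aggregation. Includes synthetic reference-population and trial-cohort
    generators with known ground truth, robust trial statistics (exact
    Wilcoxon signed-rank, biweight midcorrelation, responder logistic
    regression), and an end-to-end reproducible analysis pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    flexsurv,
    survival,
    withr
Config/testthat/edition: 3
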
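Package: tavrseal
Title: Virtual Deployment and Skirt Sealing Analysis of Self-Expanding
    Transcatheter Aortic Valves in Parametric Bicuspid and Tricuspid Roots
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale re-implementation of a patient-specific transcatheter
    aortic valve replacement (TAVR) sealing analysis. Generates parametric,
    region-labeled aortic-root surface meshes for tricuspid and bicuspid
    (Sievers type 0 and 1) morphologies with calcification, builds parametric
    self-expanding frame models with an attached sealing skirt, deploys them
    by per-node radial equilibrium against region-dependent tissue
    resistance, quantifies skirt apposition and malapposition per anatomical
    region by normal-direction ray casting (1 mm threshold), measures frame
    cross-sections at standard device levels, and runs the cohort statistics
    stage (pooled t, exact Mann-Whitney U, Fisher exact, univariate
    screening at p < 0.1 and stepwise multivariate linear regression) on
    seeded synthetic cohorts emulating the study population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
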
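Package: cytolv
Title: Latent-Variable Profiling of Multiplex Cytokine Panels
Version: 0.1.0
Authors@R:
    person("cytolv", "maintainers", email = "cytolv@example.org",
           role = c("aut", "cre"))
Description: Multivariate profiling of multiplex immunoassay (Luminex-type)
    cytokine panels. Implements z-scored partial least squares discriminant
    analysis (PLSDA) and regression (PLSR) via NIPALS, an objective-driven
    orthogonal rotation of the first two latent variables, Monte-Carlo
    subsampling with sign correction for loading stability, and composite
    score statistics (Welch ANOVA with Dunnett T3 pairwise comparisons,
    Pearson correlation, ROUT outlier removal). Includes a synthetic
    cytokine-panel generator with known ground truth for validation, plus a
    command-line pipeline driver.
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
    optparse
Suggests: testthat (>= 3.0.0), yaml, withr
Config/testthat/edition: 3
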
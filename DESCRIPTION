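Package: redcam
Title: Simulated Camera Calibration Study of Conjunctival Redness Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how smartphone camera calibration, lighting and
    optical magnification affect objective quantification of bulbar
    conjunctival redness. Provides a synthetic-data generator (24-patch color
    charts, conjunctiva scenes with controllable vessel coverage, a parametric
    camera forward model, and simulated clinician graders on the Efron scale),
    chart-based white balance and color-correction-matrix estimation,
    four pixel-level redness metrics computed over a region of interest with
    saturated-zone exclusion, and the accompanying statistics: within-subject
    standard deviation, Bland-Altman limits of agreement, Pearson correlation,
    balanced within-subjects factorial repeated-measures ANOVA and Bonferroni
    pairwise comparisons. A pipeline orchestrates the full simulated study from
    one configuration and renders a summary report.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
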
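Package: gridfa
Title: Grid-Based Quantification of Retinal Nonperfusion on Widefield Angiograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for grid-based grading of retinal perfusion on ultra-widefield
    fluorescein angiograms. Builds an equal-area concentric grid of 289 cells,
    standardizes images to the grid frame with a fovea/optic-disc landmark
    similarity transform, models per-cell ordinal perfusion grades with region
    aggregation, and computes inter-rater agreement statistics (weighted Cohen's
    kappa, Kendall's tau-b, Bland-Altman limits of agreement) with image-level
    bootstrap confidence intervals. Includes a synthetic angiogram phantom and
    simulated-grader generator so the full pipeline is testable without patient
    data, and a command-line interface for reproducible runs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    png,
    tiff,
    withr,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
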
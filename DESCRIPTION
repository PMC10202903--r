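Package: ellipsekin
Title: Kinematics, Geometry and Speed-Curvature Power Law of Elliptical
    Drawing Movements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for continuous elliptical drawing (pen
    trajectory) recordings: zero-phase Butterworth filtering, finite-difference
    kinematics, centroid-angle cycle segmentation with the first/last-cycle
    exclusion rule, direct least-squares ellipse fitting, per-cycle geometric
    and kinematic features, the log-log speed-curvature power-law fit (beta
    exponent and velocity gain factor), intra-trial variability (coefficient
    of variation), cross-hand accuracy and precision correlations, Steiger
    tests for dependent correlations, and Aligned Rank Transform factorial
    ANOVA with Tukey post hocs and partial eta squared. Includes a synthetic
    trajectory and cohort generator with controllable power-law exponent,
    per-cycle jitter, subject idiosyncrasy and cross-hand correlation, so the
    whole pipeline is testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
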
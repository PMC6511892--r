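Package: classa
Title: Classification Angle Metrics for Heart Rate Variability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing sympathetic and parasympathetic cardiac
    dynamics from RR-interval (heart rate variability) series using the
    Classification Angle (ClassA) framework: a second-order-difference-plot
    built from three-point forward derivative estimates, per-point angles and
    quadrant occupancy proportions at two temporal scales, and the Real Angle
    Sum trend statistic. Includes RR-interval conditioning (uniform
    resampling, per-window outlier replacement, coarse-graining), the
    traditional comparison metrics (heart rate, SDNN, periodogram LF/HF band
    powers, sample entropy, permutation entropy), a nonparametric statistical
    battery (Kruskal-Wallis, Bonferroni-corrected pairwise tests, Spearman
    correlation matrices), an end-to-end windowed analysis pipeline for
    multi-epoch stress-protocol recordings, and a synthetic RR-interval
    generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
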
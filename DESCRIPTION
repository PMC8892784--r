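Package: rhythmshift
Title: Ensemble Circadian Rhythm Detection and Shift-Work Differential
    Expression Analysis for Heart Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for around-the-clock bulk RNA-seq designs
    comparing control and shift-work groups. Provides six per-gene
    rhythmicity detectors (cosinor harmonic regression, Lomb-Scargle,
    JTK_CYCLE-style Kendall concordance, ARSER-style autoregressive
    spectral estimation, RAIN-style umbrella rank test, and a spectral
    F24 permutation test) combined per gene with Fisher's method under
    Benjamini-Hochberg false-discovery-rate control; a time-agnostic
    nonparametric differential-expression screen (Kruskal-Wallis omnibus,
    Mann-Whitney post hoc, compact letter display, pattern categories);
    and disease-signature scoring of results against cardiac-hypertrophy
    gene modules (Fisher's exact enrichment versus a null module,
    expression-shift distributions, and quantile-normalized
    Kolmogorov-Smirnov comparisons). A synthetic-data generator emulates
    the 3-group x 6-timepoint x 3-replicate design with planted ground
    truth for recovery testing.
License: MIT
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
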
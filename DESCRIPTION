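Package: dggeprof
Title: Analysis of DGGE Community Fingerprints: Lane Alignment, Band
    Statistics and Discriminant Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the quantitative analysis of denaturing gradient gel
    electrophoresis (DGGE) community fingerprints, built around a faecal
    16S rRNA V3 profiling study design with healthy control, ulcerative
    colitis and irritable bowel syndrome groups. Provides a synthetic gel
    simulator (group-structured multi-band lane profiles, synthetic-standard
    reference lanes, within- and between-gel distortion), lane extraction
    from 16-bit gel images, a two-stage synthetic-standard-anchored
    alignment onto a canonical 1001-point Rf grid with truncation and
    per-lane scaling, band-level statistics (peak-picked band counts,
    intensity-weighted Shannon diversity, tolerance-matched Dice
    similarity, replicate averaging, one-way ANOVA with Bonferroni pairwise
    comparisons), and chemometric group discrimination (NIPALS PLS-DA with
    leave-sample-out cross-validation, y-scrambling permutation testing,
    canonical variate analysis and loading-based discriminant-band
    ranking).
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
    mixOmics
Config/testthat/edition: 3
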
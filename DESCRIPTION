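Package: sarcoscreen
Title: Integrated ANOVA-Logrank Screening of Sarcoma Expression Profiles
    with Permutation minP Correction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Gene screening for soft tissue sarcoma expression cohorts.
    Combines a knowledge-based probe prefilter cascade (control and
    cross-hybridizing probe removal, absent-call and percentile-range
    filters, disease-gene knowledge map) with an integrated statistic
    p' = p1 x p2 formed from a subtype-discrimination one-way ANOVA
    p-value and a median-split logrank survival p-value, corrected for
    multiple testing by a permutation-constructed null distribution of
    per-repetition minimum p' (single-step minP, family-wise error
    controlled).  Includes from-scratch implementations of the component
    statistics (logrank, Kaplan-Meier, binary-covariate Cox, Welch's t,
    Spearman rank correlation, Benjamini-Hochberg step-up, standardized
    PCA, complete-linkage clustering), downstream characterization of
    selected probes, a per-subtype percentile threshold-scan survival
    screen, and a synthetic sarcoma cohort generator with planted
    diagnostic and prognostic effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    optparse
Config/testthat/edition: 3
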
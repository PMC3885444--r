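Package: glatcomp
Title: Transcriptional Comparability Analysis for Branded and Generic Complex Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares the biological impact of a generic complex drug with its
    branded counterpart and a reference standard using bulk transcriptional
    profiles. Implements batch-consistency quality control (per-probe variance
    F-tests with an activation-variability filter, reference-standard tolerance
    ranges, variance-ratio ranking, coefficient-of-variation analysis and a
    subsampling sensitivity analysis), a multi-method differential-expression
    consensus (per-probe ANOVA, empirical-Bayes moderated t, Welch t,
    signal-to-noise ratio with permutation p-values, Wilcoxon rank-sum,
    Benjamini-Hochberg FDR), ANOVA-based condition-pattern identification,
    gene-set enrichment (weighted Kolmogorov-Smirnov running sum with
    permutation null), hypergeometric over-representation with a minimum
    overlap rule, immune cell-type specificity scoring and enrichment, and a
    seeded synthetic-study generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    limma,
    sva,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
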
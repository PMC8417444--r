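Package: corvote
Title: Cross-Cohort Expression Correlation Meta-Analysis with
    Sign-Consistency Vote Filtering
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for meta-analysing gene expression correlations across
    multiple tumour cohorts. For each cohort every gene is correlated with
    an anchor gene (log2 Pearson) and with a binary clinical status
    (point-biserial), significance is assessed with the t approximation on
    n-2 degrees of freedom, and genes are retained when significantly
    correlated with a consistent sign in at least K of D cohorts, with
    conflicting cohorts penalising the vote. Downstream analyses include
    signed-list overlap (Venn) statistics, Fisher exact gene-set
    over-representation with Benjamini-Hochberg FDR control, Kaplan-Meier
    survival with an optimal-cutoff logrank scan, four-group survival from
    combined binary expression tracks, and subtype association tests
    (Kruskal-Wallis, Welch ANOVA). A seeded multi-cohort synthetic data
    generator with planted antagonistic gene modules makes the entire
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
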
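Package: blastscore
Title: Immunophenotype Scoring Systems for Blastoid B-Cell Neoplasms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements two additive immunophenotype scoring systems used in
    hematopathology to distinguish high-grade B-cell lymphoma with blastoid
    morphology (blastoid HGBL) from B-lymphoblastic leukemia/lymphoma (B-ALL):
    a six-point system built on flow-cytometry staining patterns (CD45, CD10,
    CD20, CD38, TdT) plus MYC overexpression or rearrangement, and a
    three-point immunohistochemistry-focused system (BCL6, TdT, MYC).  Also
    provides the combined decision algorithm that short-circuits on cyclin
    D1/CCND1 (mantle cell lymphoma exclusion) and CD34 positivity and resolves
    discordant scores with ancillary clinical and genetic evidence;
    diagnostic-performance evaluation (sensitivity, specificity, predictive
    values, accuracy, between-system concordance); two-sided Fisher exact
    group comparisons; a seeded synthetic cohort generator parameterised by
    published marker prevalences; and a deterministic fixture cohort
    reconstructing the published score cross-tabulation for end-to-end tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    utils,
    withr,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
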
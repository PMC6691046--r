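Package: cytofuse
Title: Multi-Tube Mass Cytometry Profile Merging, Clustering and Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Combines single-sample mass cytometry (CyTOF) profiles acquired
    under different antibody panels into one high-dimensional profile by
    matching cells across panels on a shared backbone of markers, using
    acceptable (distance-thresholded) and non-ambiguous (mutual) nearest
    neighbors. Downstream stages mirror a standard immunophenotyping
    workflow: density-dependent downsampling and agglomerative clustering
    with full upsampling, categorical marker-expression heatmaps with
    rule-based population annotation, enrichment-trend classification of
    cluster abundances, and non-parametric permutation tests for group
    comparisons. A synthetic multi-panel cohort generator with ground-truth
    cell identities makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
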
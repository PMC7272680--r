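Package: fosnet
Title: c-Fos Functional Connectivity Networks and Hippocampal
    Neurogenesis Statistics
Version: 0.1.0
Authors@R:
    person("fosnet", "developers", email = "fosnet@example.org",
           role = c("aut", "cre"))
Description: Correlation-based functional connectomics from regional
    immediate-early-gene (c-Fos) expression densities, together with
    adult hippocampal neurogenesis quantification statistics. Builds
    per-group interregional Pearson correlation matrices, binarizes
    them with a dual significance/effect-size threshold into adjacency
    matrices, and summarises the resulting graphs by node degree and
    network density. Converts per-section marker counts (doublecortin,
    BrdU, pyknotic nuclei) and traced dentate gyrus areas into
    area-standardized densities and baseline-normalized percent-change
    values, and tests group differences with unbalanced two-way
    factorial ANOVA (Type-III sums of squares) followed by
    Student-Newman-Keuls post hoc comparisons. A seeded synthetic
    cohort generator with planted block covariance and age-, sex- and
    treatment-dependent neurogenesis trajectories makes every stage
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
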
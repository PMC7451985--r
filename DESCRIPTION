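Package: pleioscope
Title: Dissecting Vertical and Horizontal Pleiotropy from Hierarchical Single-Cell Trait Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Partitions trait-pair correlations measured on single cells from
    clonal populations into pooled within-strain (environmental, r_W) and
    between-strain (genetic, r_B) components, and uses the comparison to
    classify pleiotropy as vertical (traits correlated within clones) or
    horizontal (correlation induced or strengthened by genetic variation).
    Includes Haley-Knott QTL interval mapping with permutation thresholds and
    5-cM locus clustering, alternating-conditional-expectations maximal
    correlation, weighted clustering coefficients with permutation nulls,
    cell-cycle pseudotime binning, allele-split analysis of QTL effects on
    correlations, mutation-accumulation outlier detection, dose-response
    correlation deltas, and a synthetic-data generator with known genetic
    architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
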
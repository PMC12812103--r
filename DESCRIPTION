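Package: gliovar
Title: Germline Variant Prioritization and Gene-Burden Analysis for Glioma Predisposition Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing germline whole-exome variant tables from
    familial glioma cohorts. Implements a four-category candidate-gene
    pathogenicity cascade over cancer predisposition gene (CPG) and
    glioma-risk gene panels, a case-control per-gene rare-variant
    collapsing burden test with bespoke qualifying-variant rules, a
    zero-control/three-case gene gate, two-sided Fisher's exact tests and
    the Benjamini-Krieger-Yekutieli two-stage false discovery rate
    procedure, genotype-phenotype statistics (diagnostic yield by family
    type, age-at-diagnosis comparisons, histology enrichment), the
    immunohistochemistry immunoreactivity score, panel tumor mutational
    burden, and a tumor second-hit screen. A synthetic-cohort generator
    with planted per-gene carrier enrichments makes every stage testable
    without access to patient-level sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
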
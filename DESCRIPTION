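Package: cyclederg
Title: Cell Cycle Gene-Set Deregulation, Survival and Drug-Response Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies deregulation of a gene set (for example the cell
    cycle genes) in tumor expression cohorts by comparing the set's median
    log2 expression against all other genes, with a rank-sum test and an
    empirical permutation null; stratifies patient survival by expression
    quartiles with Kaplan-Meier curves and the log-rank test; performs
    treated-versus-control differential expression with
    Benjamini-Hochberg correction and hypergeometric over-representation
    of gene sets; and implements bench quantification: four-parameter
    logistic dose-response fits with inhibitory concentrations and
    bootstrap confidence intervals, 2^-ddCt qPCR fold changes,
    densitometry ratios, colony-formation percentages, cell-cycle phase
    fold changes and xenograft tumor metrics. A synthetic-data module
    generates expression matrices, survival tables, treatment
    microarrays, viability curves and CT tables with known ground truth
    so every stage can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    survival,
    minpack.lm,
    jsonlite,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
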
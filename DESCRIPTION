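Package: cernaflow
Title: Multi-Omics ceRNA Network Inference and Methylation Integration
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for two-group (case versus
    control) multi-omics cohorts profiling mRNA, miRNA, lncRNA and DNA
    methylation. Implements probe filtering, quantile normalization,
    two-group differential expression and differential methylation with
    Benjamini-Hochberg false discovery control, removal of tissue-confounded
    signatures against a paired reference cohort, cross-layer Pearson
    correlation networks intersected with miRNA target predictions,
    competing-endogenous-RNA (ceRNA) triad assembly, nine-quadrant
    methylation-expression integration, and enrichment analysis
    (hypergeometric over-representation, weighted Kolmogorov-Smirnov gene
    set enrichment with permutation normalization, and correlation-ranked
    guilt-by-association functional prediction). Ships a synthetic-cohort
    generator with planted ground truth so the whole pipeline is testable
    end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
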
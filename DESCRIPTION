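Package: comormine
Title: Literature-Based Comorbidity Mining and Multimorbidity Gene-Set
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mines disease co-occurrence from MEDLINE/PubMed-format
    literature records using a MeSH disease lexicon, ranks co-occurring
    diseases for an index disease by the fraction of its pairing articles
    that mention each co-disease (the sort ratio), assesses comorbidity
    significance with one-sided Fisher exact tests computed in log space
    (stable down to p-values near the double-precision floor), and groups
    genes shared across an index disease and its comorbid diseases by
    exact disease-membership signature to produce multimorbidity tables.
    Includes a synthetic-corpus and synthetic-gene-set generator with
    planted associations so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
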
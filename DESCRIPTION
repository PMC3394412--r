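Package: domainscape
Title: Domain-Centric Mutational Landscapes of Somatic Mutations in Cancer Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps per-patient somatic coding mutations onto genes and onto
    individual protein-domain instances, scores length-normalized mutation
    frequencies with a Bernoulli-standardized z statistic, and calls
    significantly mutated gene and domain "peaks" with an empirical-null local
    false discovery rate.  Includes peak-origin analysis (domain peaks formed
    by aggregation across non-significant genes, and peaks retained after
    removal of significant gene peaks), cross-cohort landscape comparison,
    GO-term enrichment with ancestor propagation, deterministic landscape-map
    layout, and a synthetic cohort generator with planted driver regions for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
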
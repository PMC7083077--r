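Package: secfindr
Title: Actionable Secondary-Findings Triage for Exome Cohorts
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Triage of medically actionable secondary findings in multi-sample
    exome cohorts. Filters a cohort VCF against the 59-gene ACMG actionable
    panel using an ordered cascade (panel membership, protein-altering
    consequence, population allele frequency, ClinVar-style assertion, and
    per-genotype depth/quality/allele-balance QC), combines ACMG-AMP evidence
    codes into five-tier classifications, applies inheritance-aware reporting
    rules (dominant, X-linked, biallelic-recessive, carrier), and computes
    cohort prevalence summaries. A deterministic synthetic-cohort simulator
    spikes catalogued pathogenic variants into a background of common, benign,
    low-quality and off-panel variation so every pipeline behaviour is testable
    without protected data.
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
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    vcfR,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
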
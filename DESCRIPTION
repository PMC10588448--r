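Package: rvburden
Title: Rare-Variant Gene-Collapsing Burden Tests Against Population Controls
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Germline rare-variant burden analysis for case cohorts tested
    against public population allele-frequency controls. Reads multi-sample
    germline VCFs with per-genotype read support, applies genotype- and
    site-level quality filters, selects candidate variants by consequence
    class, population frequency and CADD deleteriousness, assigns
    population-rarity tiers, collapses qualifying alleles per gene, cohort
    subset and rarity tier, and tests enrichment with exact 2x2 inference
    (one- and two-sided Fisher tests, conditional maximum-likelihood odds
    ratios) and Benjamini-Hochberg or Bonferroni adjustment. Includes a
    synthetic-cohort generator with known enrichment structure for
    calibration and power checks.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
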
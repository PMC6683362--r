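Package: hybridogen
Title: Ploidy and Hybridogenetic Structure in Water-Frog Populations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to characterize hybridogenetic water-frog (Pelophylax)
    populations from reduced-representation sequencing and microsatellite
    data: discovery of species-diagnostic loci from parental reference
    panels, ploidy inference (diploid LR versus triploid LLR/LRR) from
    per-allele sequencing depth at diagnostic loci, triploid detection
    from microsatellite peak-height ratios against calibrated ranges,
    population summaries (observed heterozygosity and a diagnostic-locus
    hybrid index), a deterministic gamete and cross model of hybridogenetic
    breeding systems with sex-chromosome linkage, and a synthetic-cohort
    simulator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
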
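Package: secondhit
Title: Detection and Quantification of Somatic Second Hits in Normal Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis workflow for detecting and quantifying somatic "second
    hits" in a recessively acting cancer-predisposition gene (the motivating
    case is NF1 in neurofibromatosis type 1) across histologically normal
    tissues. Provides haplotype-resolved loss-of-heterozygosity calling via a
    purity-adjusted exact binomial test on tumor-phased SNPs, error-aware
    presence genotyping of candidate point mutations by pooled-control
    Fisher tests, a permutation test for shared somatic ancestry between
    tissues carrying the same second hit, a single-gene dN/dS estimator for
    truncating and missense selection, duplex (two-strand) consensus variant
    calling, tiered driver annotation of small variants, copy-number
    segments and structural variants, a mixed-effects mutation-burden test
    for recent clonal expansion, and a synthetic cohort simulator that
    supplies ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    nlme,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    yaml,
    vcfR
Config/testthat/edition: 3
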
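#!/usr/bin/env Rscript
# Stage 3: phase chromosome-17 SNPs using the tumor's complete LOH (the
# allele with the greater tumor VAF lies on the retained, mutant haplotype),
# then test every other sample for allelic imbalance with the purity-
# adjusted two-sided exact binomial test, BH-corrected across samples, and
# flag LOH second-hit clones behind the q < 0.01 / >= 30x median coverage /
# < 1% purity gates.

suppressPackageStartupMessages(library(secondhit))

snps <- read_tsv("results/het_snps.tsv")
rc <- read_tsv("results/proband_read_counts.tsv")
purity <- read_tsv("results/purity.tsv")
info <- read_tsv("results/sample_info.tsv")
tumor_id <- info$sample_id[info$is_tumor][1]

phased <- phase_by_tumor(snps, rc[rc$sample_id == tumor_id, ])
write_tsv(phased, "results/phased_snps.tsv")
cat(sprintf("phased %d/%d SNPs against tumor %s (%d dropped)\n",
            nrow(phased), nrow(snps), tumor_id, attr(phased, "dropped")))

calls <- test_loh(rc[rc$sample_id != tumor_id, ], phased, purity)
write_tsv(calls, "results/loh_calls.tsv")

flagged <- calls[calls$flagged, ]
cat(sprintf("%d sample(s) carry an allelic-imbalance second hit:\n",
            nrow(flagged)))
for (i in seq_len(nrow(flagged))) {
  cat(sprintf("  %-12s q = %.2g, %s; clone fraction %4.1f%% (CN-LOH) / %4.1f%% (deletion)\n",
              flagged$sample_id[i], flagged$q_value[i],
              flagged$direction[i],
              100 * flagged$clone_fraction_cnloh[i],
              100 * flagged$clone_fraction_deletion[i]))
}
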
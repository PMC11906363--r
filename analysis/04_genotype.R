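#!/usr/bin/env Rscript
# Stage 4: error-aware genotyping of the candidate point second hits in
# every sample. The locus-specific error rate comes from pooling the two
# unaffected controls' read counts at the same sites; presence is a
# one-sided Fisher test on summed counts, BH-corrected, present at q < 0.01.

suppressPackageStartupMessages(library(secondhit))

cand <- read_tsv("results/candidate_sites.tsv")
rc <- read_tsv("results/proband_read_counts.tsv")
ctl <- read_tsv("results/control_read_counts.tsv")

calls <- genotype_presence(cand, rc, ctl)
write_tsv(calls, "results/genotype_calls.tsv")

for (m in unique(calls$mutation_id)) {
  hit <- calls$sample_id[calls$mutation_id == m & calls$present]
  cat(sprintf("candidate %s present in %d sample(s): %s\n", m, length(hit),
              paste(hit, collapse = ", ")))
}
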
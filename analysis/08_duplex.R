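#!/usr/bin/env Rscript
# Stage 8: duplex (two-strand) consensus calling at the candidate second-hit
# sites and the germline site. A call needs variant support on both strands
# of at least one molecule and absence from the matched-normal call set
# (here, the germline variant).

suppressPackageStartupMessages(library(secondhit))
seed <- 1L

cfg <- read_cohort_config("results/cohort_config.json")
ch <- simulate_cohort(cfg, seed)
pb <- ch$proband
cand <- read_tsv("results/candidate_sites.tsv")
sites <- rbind(cand[, c("chrom", "pos", "ref", "alt")], pb$germline)

bundles <- do.call(rbind, lapply(pb$samples[-1], function(s) {
  emit_duplex_reads(pb, s, sites, single_strand_error = 1e-3,
                    seed = derive_seed(seed, "duplex"),
                    reads_per_strand = 2)
}))
calls <- call_duplex(bundles, matched_normal_calls = pb$germline)
write_tsv(calls, "results/duplex_calls.tsv")

called <- calls[calls$called, ]
cat(sprintf("duplex coverage: %d molecule-site observations across %d samples\n",
            sum(calls$duplex_coverage), length(unique(calls$sample_id))))
cat(sprintf("%d duplex call(s); germline site suppressed by the matched normal in all samples\n",
            nrow(called)))
for (i in seq_len(nrow(called))) {
  cat(sprintf("  %-12s %s:%d %s>%s  %d/%d duplex molecules\n",
              called$sample_id[i], called$chrom[i], called$pos[i],
              called$ref[i], called$alt[i], called$n_duplex_support[i],
              called$duplex_coverage[i]))
}
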
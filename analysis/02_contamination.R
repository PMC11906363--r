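#!/usr/bin/env Rscript
# Stage 2: quantify tumor contamination of every sample by pooling read
# counts at truncal tumor mutations (diploid-het sites off the LOH
# chromosome; aggregate VAF doubles to the tumor cell fraction). Samples at
# or above 1% purity are excluded from all "normal tissue" claims later.

suppressPackageStartupMessages(library(secondhit))

truncal <- read_tsv("results/truncal_sites.tsv")
rc <- read_tsv("results/proband_read_counts.tsv")
purity <- estimate_purity_all(truncal, rc)
write_tsv(purity, "results/purity.tsv")

cat(sprintf("purity over %d truncal sites:\n", nrow(truncal)))
for (i in order(-purity$purity)) {
  cat(sprintf("  %-12s %6.4f [%6.4f, %6.4f]%s\n", purity$sample_id[i],
              purity$purity[i], purity$ci_low[i], purity$ci_high[i],
              if (purity$purity[i] >= 0.01 &&
                  !startsWith(purity$sample_id[i], "PB_T"))
                "  <- fails the <1% gate" else ""))
}
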
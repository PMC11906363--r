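#!/usr/bin/env Rscript
# Stage 7: tiered driver annotation. The planted truncating point hits,
# a synonymous passenger, example copy-number segments at both ploidy
# regimes, and example structural variants are pushed through the explicit
# driver rules.

suppressPackageStartupMessages(library(secondhit))

roles <- load_gene_roles()
hotspots <- load_hotspots()
fusions <- load_known_fusions()

calls <- rbind(
  classify_small_variant(list(gene = "NF1", consequence = "nonsense",
                              residue = 304L), roles, hotspots),
  classify_small_variant(list(gene = "NF1", consequence = "missense",
                              residue = 489L), roles, hotspots),
  classify_small_variant(list(gene = "NF1", consequence = "synonymous",
                              residue = 120L), roles, hotspots),
  classify_copy_number(list(chrom = "4", start = 54e6, end = 55e6,
                            total_cn = 6, sample_ploidy = 2.0),
                       "PDGFRA", roles),
  classify_copy_number(list(chrom = "4", start = 54e6, end = 55e6,
                            total_cn = 8, sample_ploidy = 3.0),
                       "PDGFRA", roles),
  classify_copy_number(list(chrom = "17", start = 7.5e6, end = 7.9e6,
                            total_cn = 0, sample_ploidy = 2.0),
                       "TP53", roles),
  classify_structural(list(type = "deletion",
                           breakpoint_genes = c("NF1", "NF1")),
                      roles, fusions),
  classify_structural(list(type = "translocation",
                           breakpoint_genes = c("KIAA1549", "BRAF")),
                      roles, fusions))
write_tsv(calls, "results/driver_calls.tsv")
print(calls, row.names = FALSE)
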
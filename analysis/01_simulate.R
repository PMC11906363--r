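#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# One predisposed child (heterozygous germline truncating hit in an NF1-like
# gene on chromosome 17; tumor with complete chr17 CN-LOH retaining the
# mutant haplotype; normal tissues seeded with independent second-hit clones
# at fractions 2-56%) and two unaffected controls. Writes every table the
# later stages consume, so each stage can be re-run standalone.

suppressPackageStartupMessages(library(secondhit))
seed <- 1L
dir.create("results", showWarnings = FALSE)

cfg <- default_cohort_config()
write_cohort_config(cfg, "results/cohort_config.json")
ch <- simulate_cohort(cfg, seed)
pb <- ch$proband

# read counts at the SNP panel, all somatic mutations and the germline hit
sites <- rbind(snp_sites(pb),
               mutation_sites(pb, include_germline = TRUE)[,
                 c("chrom", "pos", "ref", "alt")])
rc <- emit_all_read_counts(pb, sites, derive_seed(seed, "reads"))
write_tsv(rc, "results/proband_read_counts.tsv")

somatic <- mutation_sites(pb)
ctl_rc <- do.call(rbind, lapply(ch[-1], function(ctl) {
  emit_all_read_counts(ctl, somatic[, c("chrom", "pos", "ref", "alt")],
                       derive_seed(seed, paste0("ctl_reads_", ctl$id)))
}))
write_tsv(ctl_rc, "results/control_read_counts.tsv")

# ground truth the downstream stages need as plain files
write_tsv(pb$snps[, c("chrom", "pos", "ref", "alt")],
          "results/het_snps.tsv")
truncal <- pb$tree$catalog[pb$tree$catalog$mutation_id %in%
                             truncal_mutations(pb) &
                             pb$tree$catalog$chrom != pb$gene$chrom, ]
write_tsv(truncal, "results/truncal_sites.tsv")
cand <- pb$tree$catalog[pb$tree$catalog$mutation_id %in%
                          pb$clones$point_mutation_id[pb$clones$type ==
                                                        "point"], ]
write_tsv(cand, "results/candidate_sites.tsv")
somatic_nontruncal <- somatic[!(somatic$mutation_id %in%
                                  truncal_mutations(pb)), ]
write_tsv(somatic_nontruncal, "results/somatic_sites.tsv")
write_simple_vcf(rbind(pb$germline,
                       pb$tree$catalog[, c("chrom", "pos", "ref", "alt")]),
                 "results/proband_variants.vcf")

point_nodes <- pb$clones$node_id[pb$clones$type == "point"]
info <- do.call(rbind, lapply(pb$samples, function(s) {
  nodes <- as.integer(names(s$clone_fractions))
  on_path <- function(target) any(vapply(nodes, function(n)
    target %in% root_path(pb$tree, n), logical(1)))
  data.frame(sample_id = s$sample_id, modality = s$modality,
             stratum = s$stratum, tissue_piece_id = s$tissue_piece_id,
             target_depth = s$target_depth,
             is_tumor = on_path(pb$tumor$node) &&
               s$tumor_contamination == 0 && s$sample_id == "PB_T",
             has_second_hit = any(vapply(pb$clones$node_id, on_path,
                                         logical(1))),
             carries_point_hit = any(vapply(point_nodes, on_path,
                                            logical(1))),
             stringsAsFactors = FALSE)
}))
write_tsv(info, "results/sample_info.tsv")

cat(sprintf("simulated %d proband samples (%d with a second hit), %d SNPs, %d somatic mutations\n",
            nrow(info), sum(info$has_second_hit), nrow(pb$snps),
            nrow(pb$tree$catalog)))
cat(sprintf("planted clones: %s\n",
            paste(sprintf("%s (node %d, %s)", pb$clones$clone_id,
                          pb$clones$node_id, pb$clones$type),
                  collapse = ", ")))
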
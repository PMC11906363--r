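#!/usr/bin/env Rscript
# Stage 5: are the tissues that share a second hit clonally related?
# Presence-call every somatic substitution in every normal sample against
# the control-pool error panel, count substitutions shared by each pair,
# and compare pairs that carry the same point second hit with random draws
# from unrelated clean CNS pairs (one-sided permutation test, 1,000 draws).

suppressPackageStartupMessages(library(secondhit))
seed <- 1L

somatic <- read_tsv("results/somatic_sites.tsv")
rc <- read_tsv("results/proband_read_counts.tsv")
ctl <- read_tsv("results/control_read_counts.tsv")
info <- read_tsv("results/sample_info.tsv")
purity <- read_tsv("results/purity.tsv")

normals <- info$sample_id[!info$is_tumor]
presence <- genotype_presence(somatic, rc[rc$sample_id %in% normals, ],
                              ctl, min_alt = 2)
write_tsv(presence[presence$present, c("mutation_id", "sample_id")],
          "results/presence_calls.tsv")

carriers <- info$sample_id[info$carries_point_hit & !info$is_tumor]
clean <- merge(info, purity)
ctl_ids <- clean$sample_id[!clean$has_second_hit & !clean$is_tumor &
                             clean$purity < 0.01 & clean$stratum == "CNS"]
test <- pairwise_sharing(presence, carriers, group = "test")
pool <- pairwise_sharing(presence, ctl_ids, group = "control")
write_tsv(rbind(test, pool), "results/pair_sharing.tsv")

res <- permutation_test(test$shared_count, pool$shared_count,
                        n_draws = 1000, seed = derive_seed(seed, "perm"))
jsonlite::write_json(unclass(res), "results/permutation.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat(sprintf("test pairs (same point hit): mean %0.1f shared substitutions over %d pair(s)\n",
            res$test_mean, res$n_test_pairs))
cat(sprintf("control pairs (clean CNS): mean %0.1f over %d pair(s)\n",
            mean(pool$shared_count), nrow(pool)))
cat(sprintf("one-sided permutation P %s: tissues sharing the hit descend from a common ancestor\n",
            if (res$exceed_count == 0) res$p_display
            else paste("=", res$p_display)))
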
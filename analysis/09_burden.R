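#!/usr/bin/env Rscript
# Stage 9: is second-hit-null status compatible with a recent clonal
# expansion? Per-sample substitution counts (presence calls from stage 5)
# are modeled with a linear mixed model: null status, modality and coverage
# as fixed effects, tissue piece as a random intercept. A recent expansion
# would add on the order of 100 mutations; the fitted effect is compared
# against that yardstick.

suppressPackageStartupMessages(library(secondhit))

presence <- read_tsv("results/presence_calls.tsv")
info <- read_tsv("results/sample_info.tsv")
info <- info[!info$is_tumor, ]

counts <- table(factor(presence$sample_id, levels = info$sample_id))
recs <- data.frame(sample_id = info$sample_id,
                   substitution_count = as.integer(counts),
                   nf1_null = info$has_second_hit,
                   modality = info$modality,
                   coverage = info$target_depth,
                   tissue_piece_id = info$tissue_piece_id,
                   stringsAsFactors = FALSE)
write_tsv(recs, "results/burden_records.tsv")

fit <- fit_burden_model(recs)
jsonlite::write_json(list(effect = fit$effect, se = fit$se,
                          p_value = fit$p_value,
                          expansion_verdict = fit$expansion_verdict,
                          model = fit$model),
                     "results/burden_model.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
print(fit)
cat(if (fit$expansion_verdict)
  "burden is compatible with a recent clonal expansion\n" else
  "burden is incompatible with a recent clonal expansion\n")
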
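cohort <- simulate_cohort(small_cohort_config(), seed = 42)
pb <- cohort$proband

test_that("config validation rejects over-full samples and bad topologies", {
  cfg <- small_cohort_config()
  cfg$proband$samples[[2]]$clone_fractions <- c("6" = 0.9, "7" = 0.3)
  expect_error(validate_cohort_config(cfg), "exceed 1")
  cfg2 <- small_cohort_config()
  cfg2$proband$parents[1] <- 2
  expect_error(validate_cohort_config(cfg2), "root")
})

test_that("every proband cell carries the germline hit; controls carry no second hits", {
  g <- pb$germline
  # a germline-only background population is exactly heterozygous
  bg <- list(sample_id = "bg", modality = "bulk",
             clone_fractions = c("1" = 1.0), tumor_contamination = 0,
             target_depth = 30, error_rate = 0)
  expect_equal(true_vaf(pb, bg, g), 0.5)
  # every sample carries the hit in the bulk of its cells; clones that lost
  # the mutant haplotype pull the fraction below 0.5 but never to 0
  for (s in pb$samples) {
    v <- true_vaf(pb, s, g)
    expect_gt(v, 0.4)
  }
  for (ctl in cohort[-1]) {
    expect_equal(nrow(ctl$clones), 0L)
    expect_null(ctl$germline)
  }
})

test_that("a pure tumor shows retained-allele fraction 1 at every chr17 het SNP", {
  spec <- list(sample_id = "pure_tumor", modality = "bulk",
               clone_fractions = c("3" = 1.0), tumor_contamination = 0,
               target_depth = 50, error_rate = 0)
  v <- true_vaf(pb, spec, snp_sites(pb))
  # tumor = CN-LOH retaining the mutant haplotype (hap A)
  expect_equal(v, as.numeric(pb$snps$alt_on_hap_a))
  # and the germline hit is homozygous
  expect_equal(true_vaf(pb, spec, pb$germline), 1)
})

test_that("read counts follow the clone-size = 2 x VAF law", {
  cand <- pb$clones[pb$clones$clone_id == "point_shared", ]
  site <- pb$tree$catalog[pb$tree$catalog$mutation_id == cand$point_mutation_id, ]
  spec <- list(sample_id = "deep", modality = "lcm",
               clone_fractions = c("5" = 0.56), tumor_contamination = 0,
               target_depth = 400000, error_rate = 0)
  rc <- emit_read_counts(pb, spec, site, seed = 5)
  vaf_hat <- rc$alt_depth / rc$depth
  se <- sqrt(0.28 * 0.72 / rc$depth)
  expect_lt(abs(vaf_hat - 0.28), 3 * se)  # E[VAF] = f/2, clone size = 2 VAF
})

test_that("zero target depth yields empty coverage; empty sites yield empty table", {
  spec <- pb$samples[[2]]
  spec$target_depth <- 0
  rc <- emit_read_counts(pb, spec, snp_sites(pb), seed = 1)
  expect_true(all(rc$depth == 0) && all(rc$alt_depth == 0))
  rc0 <- emit_read_counts(pb, pb$samples[[2]], snp_sites(pb)[0, ], seed = 1)
  expect_equal(nrow(rc0), 0L)
})

test_that("sites outside the simulated genome are rejected", {
  bad <- data.frame(chrom = "chrX", pos = 100, ref = "A", alt = "C")
  expect_error(emit_read_counts(pb, pb$samples[[2]], bad, seed = 1),
               "outside the simulated genome")
})

test_that("error-only sites match the binomial e/3 closed form", {
  n <- 100000
  sites <- data.frame(chrom = "2", pos = seq_len(n), ref = "A", alt = "C",
                      stringsAsFactors = FALSE)
  ctl <- cohort$control_1
  spec <- list(sample_id = "err", modality = "bulk",
               clone_fractions = c("4" = 0.95), tumor_contamination = 0,
               target_depth = 30, error_rate = 1e-3)
  rc <- emit_read_counts(ctl, spec, sites, seed = 9)
  p_alt <- 1e-3 / 3
  total <- sum(rc$depth)
  se <- sqrt(p_alt * (1 - p_alt) / total)
  expect_lt(abs(sum(rc$alt_depth) / total - p_alt), 3 * se)
})

test_that("emitted genotypes reproduce the tree-path sharing oracle without noise", {
  sites <- mutation_sites(pb)[, c("chrom", "pos", "ref", "alt")]
  mk <- function(node) list(sample_id = paste0("pure_", node),
                            modality = "lcm",
                            clone_fractions = stats::setNames(1, node),
                            tumor_contamination = 0, target_depth = 100,
                            error_rate = 0)
  for (pair in list(c(6L, 7L), c(13L, 17L))) {
    va <- true_vaf(pb, mk(pair[1]), sites)
    vb <- true_vaf(pb, mk(pair[2]), sites)
    expect_equal(sum(va > 0 & vb > 0),
                 oracle_shared_count(pb$tree, pair[1], pair[2]))
  }
})

test_that("tumor contamination drives truncal aggregate VAF to t/2", {
  tr_ids <- truncal_mutations(pb)
  sites <- pb$tree$catalog[pb$tree$catalog$mutation_id %in% tr_ids &
                             pb$tree$catalog$chrom != pb$gene$chrom, ]
  spec <- list(sample_id = "cont", modality = "bulk",
               clone_fractions = c("13" = 0.90), tumor_contamination = 0.04,
               target_depth = 1000, error_rate = 0)
  rc <- emit_read_counts(pb, spec, sites, seed = 3)
  agg <- sum(rc$alt_depth) / sum(rc$depth)
  se <- sqrt(0.02 * 0.98 / sum(rc$depth))
  expect_lt(abs(agg - 0.02), 3 * se)
})

test_that("cohort simulation is reproducible byte-for-byte", {
  a <- simulate_cohort(small_cohort_config(), seed = 42)
  expect_identical(a, cohort)
  rc1 <- emit_read_counts(pb, pb$samples[[2]], snp_sites(pb), seed = 7)
  rc2 <- emit_read_counts(pb, pb$samples[[2]], snp_sites(pb), seed = 7)
  expect_identical(rc1, rc2)
})

test_that("duplex bundles: clonal variants sit on both strands of every molecule", {
  cand <- pb$clones[pb$clones$clone_id == "point_shared", ]
  site <- pb$tree$catalog[pb$tree$catalog$mutation_id ==
                            cand$point_mutation_id,
                          c("chrom", "pos", "ref", "alt")]
  spec <- list(sample_id = "dup", modality = "lcm",
               clone_fractions = c("17" = 1.0), tumor_contamination = 0,
               target_depth = 50, error_rate = 0)
  # germline hit has dosage 0.5; use a fully clonal site instead: the
  # germline variant in a CN-LOH population is clonal at dosage 1
  spec_loh <- list(sample_id = "dup2", modality = "lcm",
                   clone_fractions = c("8" = 1.0), tumor_contamination = 0,
                   target_depth = 50, error_rate = 0)
  bd <- emit_duplex_reads(pb, spec_loh, pb$germline,
                          single_strand_error = 0, seed = 2,
                          reads_per_strand = 2)
  expect_true(all(bd$variant_reads == bd$reads))
  # zero molecules -> empty table
  spec0 <- spec; spec0$target_depth <- 0
  bd0 <- emit_duplex_reads(pb, spec0, site, single_strand_error = 0, seed = 2)
  expect_equal(nrow(bd0), 0L)
  expect_error(emit_duplex_reads(pb, spec, site, single_strand_error = 1,
                                 seed = 1), "single_strand_error")
})
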
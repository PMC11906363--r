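bundle_row <- function(mol, strand, reads, vr, pos = 100, sample = "s") {
  data.frame(molecule_id = mol, sample_id = sample, chrom = "17", pos = pos,
             ref = "G", alt = "A", strand = strand, reads = reads,
             variant_reads = vr, stringsAsFactors = FALSE)
}

test_that("single-strand support never yields a call", {
  b <- rbind(bundle_row("m1", "+", 2, 2), bundle_row("m1", "-", 2, 0))
  res <- call_duplex(b)
  expect_equal(res$n_duplex_support, 0L)
  expect_false(res$called)
  expect_equal(res$duplex_coverage, 1L)
})

test_that("both-strand support calls unless the site is in the matched normal", {
  b <- rbind(bundle_row("m1", "+", 2, 2), bundle_row("m1", "-", 2, 2))
  res <- call_duplex(b)
  expect_true(res$called)
  normal <- data.frame(chrom = "17", pos = 100, ref = "G", alt = "A")
  res2 <- call_duplex(b, normal)
  expect_true(res2$in_normal)
  expect_false(res2$called)
})

test_that("within-strand ties give no consensus", {
  b <- rbind(bundle_row("m1", "+", 2, 1), bundle_row("m1", "-", 2, 2))
  expect_false(call_duplex(b)$called)
})

test_that("min_reads_per_strand floor applies", {
  b <- rbind(bundle_row("m1", "+", 3, 2), bundle_row("m1", "-", 3, 2))
  expect_true(call_duplex(b, min_reads_per_strand = 2)$called)
  expect_false(call_duplex(b, min_reads_per_strand = 3)$called)
})

test_that("inconsistent molecule/strand keys are an input error", {
  b <- rbind(bundle_row("m1", "+", 2, 2), bundle_row("m1", "+", 2, 1),
             bundle_row("m1", "-", 2, 2))
  expect_error(call_duplex(b), "inconsistent bundle")
  bad <- bundle_row("m1", "*", 2, 1)
  expect_error(call_duplex(bad), "strand")
})

test_that("duplex coverage is invariant to variant content", {
  b1 <- rbind(bundle_row("m1", "+", 2, 0), bundle_row("m1", "-", 2, 0),
              bundle_row("m2", "+", 2, 2), bundle_row("m2", "-", 2, 2))
  b2 <- b1
  b2$variant_reads <- 0
  expect_equal(call_duplex(b1)$duplex_coverage,
               call_duplex(b2)$duplex_coverage)
})

test_that("clonal variants are recovered with probability -> 1 as coverage grows", {
  ch <- simulate_cohort(small_cohort_config(), seed = 23)
  pb <- ch$proband
  spec <- list(sample_id = "dx", modality = "lcm",
               clone_fractions = c("8" = 1.0), tumor_contamination = 0,
               target_depth = 60, error_rate = 0)
  # in the CN-LOH clone the germline site is clonal at dosage 1
  bd <- emit_duplex_reads(pb, spec, pb$germline, single_strand_error = 1e-3,
                          seed = 23, reads_per_strand = 2)
  res <- call_duplex(bd)
  expect_true(res$called)
  expect_gt(res$n_duplex_support / res$duplex_coverage, 0.95)
})

test_that("duplex false-call rate matches the (e/3)^2 analytic value", {
  ch <- simulate_cohort(small_cohort_config(), seed = 29)
  ctl <- ch$control_1
  e <- 0.06
  n_sites <- 10000
  sites <- data.frame(chrom = "3", pos = seq_len(n_sites), ref = "A",
                      alt = "C", stringsAsFactors = FALSE)
  spec <- list(sample_id = "err", modality = "bulk",
               clone_fractions = c("4" = 0.95), tumor_contamination = 0,
               target_depth = 40, error_rate = 0)
  # pool independent replicates so the Monte-Carlo estimate is not hostage
  # to a single draw
  support <- 0
  n_mol <- 0
  for (s in 1:3) {
    bd <- emit_duplex_reads(ctl, spec, sites, single_strand_error = e,
                            seed = s, reads_per_strand = 1)
    res <- call_duplex(bd)
    support <- support + sum(res$n_duplex_support)
    n_mol <- n_mol + sum(res$duplex_coverage)
  }
  rate <- support / n_mol
  p <- (e / 3)^2
  se <- sqrt(p * (1 - p) / n_mol)
  expect_lt(abs(rate - p), 3 * se)
  # and far below the single-strand error rate
  expect_lt(rate, e / 3 / 10)
})
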
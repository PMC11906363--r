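test_that("the purity-adjusted null allele fraction has the stated endpoints", {
  expect_identical(loh_null_p0(0), 0.5)
  expect_identical(loh_null_p0(1), 1.0)
  expect_equal(loh_null_p0(0.2), 0.2 + 0.8 * 0.5)
  expect_error(loh_null_p0(-0.1))
})

test_that("phasing follows the greater-allele-fraction rule and drops ties", {
  snps <- data.frame(chrom = "17", pos = 1:4, ref = "A", alt = "C",
                     stringsAsFactors = FALSE)
  rc <- rc_table("t", 1:4, depth = c(40, 40, 40, 5),
                 alt_depth = c(40, 0, 20, 5))
  ph <- phase_by_tumor(snps, rc, min_tumor_depth = 10)
  expect_equal(ph$pos, 1:2)  # tie (pos 3) and low depth (pos 4) dropped
  expect_equal(ph$retained_is_alt, c(TRUE, FALSE))
  expect_equal(attr(ph, "dropped"), 2L)
  expect_error(phase_by_tumor(snps[0, ], rc), "empty")
})

test_that("phasing recovers simulator truth at >= 99% with a 0.95-purity tumor", {
  cfg <- small_cohort_config(n_snps = 200)
  cfg$proband$samples[[1]]$target_depth <- 40
  ch <- simulate_cohort(cfg, seed = 31)
  pb <- ch$proband
  rc <- emit_read_counts(pb, "PB_T", snp_sites(pb), seed = 31)
  ph <- phase_by_tumor(pb$snps, rc)
  truth <- pb$snps$alt_on_hap_a[match(ph$pos, pb$snps$pos)]
  expect_gte(mean(ph$retained_is_alt == truth), 0.99)
})

test_that("an exact null gives p = 1 and no flag", {
  snps <- data.frame(chrom = "17", pos = 1:10, ref = "A", alt = "C",
                     retained_is_alt = TRUE, stringsAsFactors = FALSE)
  rc <- rc_table("s", 1:10, depth = 40, alt_depth = 20)
  res <- test_loh(rc, snps, c(s = 0))
  expect_equal(res$p_value, 1)
  expect_false(res$flagged)
  expect_equal(res$p0, 0.5)
  expect_equal(res$direction, "none")
})

test_that("label swap flips direction but preserves the two-sided p value", {
  snps <- data.frame(chrom = "17", pos = 1:50, ref = "A", alt = "C",
                     retained_is_alt = TRUE, stringsAsFactors = FALSE)
  set.seed(5)
  d <- rpois(50, 40)
  a <- rbinom(50, d, 0.58)
  rc <- rc_table("s", 1:50, d, a)
  res1 <- test_loh(rc, snps, c(s = 0))
  snps2 <- snps
  snps2$retained_is_alt <- FALSE
  res2 <- test_loh(rc, snps2, c(s = 0))
  expect_equal(res1$p_value, res2$p_value)
  expect_equal(res1$direction, "wt_loss")
  expect_equal(res2$direction, "mutant_loss")
  expect_equal(res1$clone_fraction_cnloh, res2$clone_fraction_cnloh)
})

test_that("a strong imbalance with only 25x median coverage is not flagged", {
  snps <- data.frame(chrom = "17", pos = 1:100, ref = "A", alt = "C",
                     retained_is_alt = TRUE, stringsAsFactors = FALSE)
  rc <- rc_table("s", 1:100, depth = 25, alt_depth = 18)  # gross imbalance
  res <- test_loh(rc, snps, c(s = 0))
  expect_lt(res$q_value, 0.01)
  expect_false(res$flagged)   # median coverage gate
  expect_equal(res$median_coverage, 25)
})

test_that("a contaminated sample is never attributed a somatic LOH clone", {
  snps <- data.frame(chrom = "17", pos = 1:100, ref = "A", alt = "C",
                     retained_is_alt = TRUE, stringsAsFactors = FALSE)
  set.seed(7)
  d <- rpois(100, 40)
  purity <- 0.05
  a <- rbinom(100, d, loh_null_p0(purity) + 0.05)
  rc <- rc_table("s", 1:100, d, a)
  res <- test_loh(rc, snps, c(s = purity))
  expect_false(res$flagged)   # purity gate, regardless of q
})

test_that("a planted CN-LOH clone is detected and its size recovered", {
  # 1,500 phased SNPs at >= 10x, mean depth 40, purity 0, clone fraction 0.13
  n <- 1500
  f <- 0.13
  snps <- data.frame(chrom = "17", pos = seq_len(n), ref = "A", alt = "C",
                     retained_is_alt = rep(c(TRUE, FALSE), length.out = n),
                     stringsAsFactors = FALSE)
  set.seed(9)
  d <- rpois(n, 40)
  p_alt <- ifelse(snps$retained_is_alt, 0.5 + f / 2, 0.5 - f / 2)
  a <- rbinom(n, d, p_alt)
  rc <- rc_table("s", seq_len(n), d, a)
  res <- test_loh(rc, snps, c(s = 0))
  expect_lt(res$q_value, 0.01)
  expect_true(res$flagged)
  expect_equal(res$direction, "wt_loss")
  expect_lt(abs(res$clone_fraction_cnloh - f), 0.03)
  # closed-form binomial power at this effect and coverage is ~1: the
  # two-sided rejection region at alpha = 0.01/1 excludes 0.5 + f/2
  trials <- sum(d)
  crit <- qbinom(c(0.005, 0.995), trials, 0.5)
  power <- pbinom(crit[1], trials, 0.5 + f / 2) +
    pbinom(crit[2], trials, 0.5 + f / 2, lower.tail = FALSE)
  expect_gt(power, 0.999)
})

test_that("samples losing the mutant allele are reported as mutant_loss", {
  n <- 500
  snps <- data.frame(chrom = "17", pos = seq_len(n), ref = "A", alt = "C",
                     retained_is_alt = TRUE, stringsAsFactors = FALSE)
  set.seed(11)
  d <- rpois(n, 40)
  a <- rbinom(n, d, 0.42)  # retained (mutant) haplotype depleted
  rc <- rc_table("s", seq_len(n), d, a)
  res <- test_loh(rc, snps, c(s = 0))
  expect_true(res$flagged)
  expect_equal(res$direction, "mutant_loss")
})

test_that("samples without qualifying SNPs are untestable, not an error", {
  snps <- data.frame(chrom = "17", pos = 1:5, ref = "A", alt = "C",
                     retained_is_alt = TRUE, stringsAsFactors = FALSE)
  rc <- rc_table("s", 1:5, depth = 3, alt_depth = 1)
  res <- test_loh(rc, snps, c(s = 0))
  expect_false(res$testable)
  expect_false(res$flagged)
  expect_true(is.na(res$p_value))
})
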
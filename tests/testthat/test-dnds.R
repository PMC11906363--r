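# independent translation oracle via Biostrings on whole sequences
oracle_impact <- function(cds, cds_pos, alt) {
  s <- strsplit(cds, "")[[1]]
  ref_aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds)))
  s[cds_pos] <- alt
  alt_aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(s, collapse = ""))))
  ci <- (cds_pos - 1) %/% 3 + 1
  r <- substr(ref_aa, ci, ci)
  a <- substr(alt_aa, ci, ci)
  if (r == a) "synonymous" else if (a == "*") "nonsense" else "missense"
}

test_that("classic codon-table cases", {
  gm <- toy_gene("ATGGGGTGG")  # Met-Gly-Trp
  it <- enumerate_impacts(gm)
  # GGG -> GGA: third-position wobble is synonymous
  expect_equal(it$impact[it$cds_pos == 6 & it$alt == "A"], "synonymous")
  # TGG (Trp) position-2 G->A gives the TAG stop
  expect_equal(it$impact[it$cds_pos == 8 & it$alt == "A"], "nonsense")
  expect_equal(nrow(it), 27)  # 3 alts per CDS base
  expect_true(all(table(it$cds_pos) == 3))
})

test_that("all substitutions of a toy gene agree with an independent translation oracle", {
  set.seed(4)
  gm <- random_gene_model(8, seed = 12, n_exons = 1)
  it <- enumerate_impacts(gm)
  for (i in seq_len(nrow(it))) {
    expect_equal(it$impact[i],
                 oracle_impact(gm$cds_sequence, it$cds_pos[i], it$alt[i]),
                 info = sprintf("cds_pos %d alt %s", it$cds_pos[i],
                                it$alt[i]))
  }
})

test_that("multi-exon genes gain truncating splice rows at intron edges", {
  gm <- random_gene_model(20, seed = 5, n_exons = 3)
  expect_equal(length(gm$splice_site_positions), 8L)  # 2 junctions x 4
  it <- enumerate_impacts(gm)
  sp <- it[is.na(it$cds_pos), ]
  expect_true(all(sp$impact == "splice"))
  expect_equal(nrow(sp), 8L * 3L)
})

test_that("CDS validation rejects malformed models", {
  expect_error(gene_model("X", "ATGG",
                          data.frame(chrom = "1", start = 1, end = 4)),
               "divisible by 3")
  expect_error(gene_model("X", "ATGNNG",
                          data.frame(chrom = "1", start = 1, end = 6)),
               "A/C/G/T")
  expect_error(gene_model("X", "ATGGGG",
                          data.frame(chrom = "1", start = 1, end = 3)),
               "sum to the CDS length")
})

test_that("expected class fractions match hand enumeration and normalize", {
  gm <- toy_gene("ATGGGGTGG")
  it <- enumerate_impacts(gm)
  e <- expected_class_fractions(it)
  hand <- table(factor(it$impact, c("synonymous", "missense", "nonsense",
                                    "splice"))) / nrow(it)
  expect_equal(unname(e["e_syn"]), unname(hand[["synonymous"]]))
  expect_equal(unname(e["e_mis"]), unname(hand[["missense"]]))
  expect_equal(unname(e["e_trunc"]),
               unname(hand[["nonsense"]] + hand[["splice"]]))
  expect_equal(sum(e), 1)

  # any random spectrum still normalizes, and scaling it changes nothing
  set.seed(6)
  ctxs <- unique(it$trinucleotide_context)
  spec <- expand.grid(context = ctxs, alt = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  spec$rate <- runif(nrow(spec))
  e1 <- expected_class_fractions(it, spec)
  expect_equal(sum(e1), 1)
  spec2 <- spec
  spec2$rate <- spec2$rate * 1000
  expect_equal(expected_class_fractions(it, spec2), e1)
})

test_that("degenerate spectra are rejected", {
  gm <- toy_gene("ATGGGGTGG")
  it <- enumerate_impacts(gm)
  zero <- data.frame(context = unique(it$trinucleotide_context), alt = "A",
                     rate = 0)
  expect_error(expected_class_fractions(it, zero))
  absent <- data.frame(context = "XXX", alt = "A", rate = 1)
  expect_error(expected_class_fractions(it, absent))
})

test_that("observed counts exactly proportional to expectation give omega = 1", {
  gm <- random_gene_model(30, seed = 7, n_exons = 1)
  it <- enumerate_impacts(gm)
  est <- estimate_dnds(it, it)   # the full enumeration as 'observed'
  expect_equal(est$omega_truncating, 1)
  expect_equal(est$omega_missense, 1)
  expect_lt(est$ci_low_truncating, 1)
  expect_gt(est$ci_high_truncating, 1)
})

test_that("the MLE equals the closed-form observed/expected ratio", {
  gm <- random_gene_model(10, seed = 9, n_exons = 1)
  it <- enumerate_impacts(gm)
  e <- expected_class_fractions(it)
  set.seed(10)
  for (i in 1:10) {
    obs <- simulate_gene_mutations(it, 40, omega_trunc = runif(1, 0.3, 8),
                                   seed = i)
    est <- estimate_dnds(obs, it)
    closed <- (est$n_trunc / e[["e_trunc"]]) / (est$n_syn / e[["e_syn"]])
    expect_equal(est$omega_truncating, closed)
  }
})

test_that("zero synonymous mutations give omega = Inf with a finite lower bound", {
  gm <- random_gene_model(30, seed = 13, n_exons = 1)
  it <- enumerate_impacts(gm)
  obs <- it[it$impact == "nonsense", ][1:10, ]
  est <- estimate_dnds(obs, it)
  expect_identical(est$omega_truncating, Inf)
  expect_true(is.finite(est$ci_low_truncating))
  expect_gt(est$ci_low_truncating, 1)
  expect_true(est$positive_selection)
})

test_that("zero observed mutations are untestable", {
  gm <- toy_gene()
  it <- enumerate_impacts(gm)
  est <- estimate_dnds(it[0, ], it)
  expect_false(est$testable)
})

test_that("neutral simulations cover 1 and selection is detected with power", {
  gm <- random_gene_model(300, seed = 20, n_exons = 1)
  it <- enumerate_impacts(gm)
  # neutral: CI covers 1 in roughly 95% of replicates (down-scaled here;
  # the acceptance suite runs the full 1,000)
  cover <- logical(300)
  omegas <- numeric(300)
  for (i in seq_len(300)) {
    obs <- simulate_gene_mutations(it, 50, seed = 1000 + i)
    est <- estimate_dnds(obs, it)
    cover[i] <- est$ci_low_truncating <= 1 && 1 <= est$ci_high_truncating
    omegas[i] <- est$omega_truncating
  }
  expect_gt(mean(cover), 0.90)
  expect_gt(median(omegas), 0.8)
  expect_lt(median(omegas), 1.25)
  # 10x truncating excess at n = 30
  hits <- vapply(1:100, function(i) {
    obs <- simulate_gene_mutations(it, 30, omega_trunc = 10, seed = 2000 + i)
    estimate_dnds(obs, it)$positive_selection
  }, logical(1))
  expect_gt(mean(hits), 0.9)
})

test_that("genome-space observed mutations classify through the exon map", {
  gm <- random_gene_model(12, seed = 21, n_exons = 2)
  it <- enumerate_impacts(gm)
  row <- it[!is.na(it$cds_pos), ][5, ]
  obs <- data.frame(pos = row$genomic_pos, alt = row$alt_genome)
  expect_equal(classify_mutations(obs, it)$impact, row$impact)
  expect_error(classify_mutations(data.frame(pos = 1, alt = "A"), it),
               "not classifiable")
})
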
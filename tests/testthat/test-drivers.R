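roles <- load_gene_roles()
hotspots <- load_hotspots()
fusions <- load_known_fusions()

test_that("NF1 small-variant rules", {
  nonsense <- classify_small_variant(list(gene = "NF1",
                                          consequence = "nonsense",
                                          residue = 304L), roles, hotspots)
  expect_equal(nonsense$verdict, "driver")
  expect_equal(nonsense$tier, "1")
  expect_equal(nonsense$rationale, "nf1_inactivating")

  hot <- classify_small_variant(list(gene = "NF1", consequence = "missense",
                                     residue = 489L), roles, hotspots)
  expect_equal(hot$verdict, "driver")   # recurrence 5 > 4

  cold <- classify_small_variant(list(gene = "NF1", consequence = "missense",
                                      residue = 176L), roles, hotspots)
  expect_equal(cold$verdict, "not_driver")  # recurrence 2
})

test_that("general small-variant rules and tiering", {
  syn <- classify_small_variant(list(gene = "TP53",
                                     consequence = "synonymous",
                                     residue = 100L), roles, hotspots)
  expect_equal(syn$verdict, "not_driver")

  lof <- classify_small_variant(list(gene = "TP53", consequence = "frameshift",
                                     residue = NA), roles, hotspots)
  expect_equal(lof$verdict, "driver")
  expect_equal(lof$tier, "1")

  lof2 <- classify_small_variant(list(gene = "SMARCB1",
                                      consequence = "nonsense", residue = NA),
                                 roles, hotspots)
  expect_equal(lof2$tier, "2")   # census gene outside the tier-1 list

  hot <- classify_small_variant(list(gene = "BRAF", consequence = "missense",
                                     residue = 600L), roles, hotspots)
  expect_equal(hot$rationale, "hotspot_in_dominant_gene")

  # LoF in a dominant-only gene is not a qualifying class
  lof3 <- classify_small_variant(list(gene = "BRAF", consequence = "nonsense",
                                      residue = NA), roles, hotspots)
  expect_equal(lof3$verdict, "not_driver")

  expect_error(classify_small_variant(list(gene = NA, consequence = "missense"),
                                      roles, hotspots), "annotated")
})

seg <- function(cn, ploidy, width = 8e6) {
  list(chrom = "4", start = 1e6, end = 1e6 + width - 1, total_cn = cn,
       sample_ploidy = ploidy)
}

test_that("amplification thresholds are exact at both ploidy regimes", {
  amp2 <- vapply(1:12, function(cn) {
    classify_copy_number(seg(cn, 2.0), "PDGFRA", roles)$verdict == "driver"
  }, logical(1))
  expect_equal(min(which(amp2)), 5)      # >= 5 when ploidy < 2.7
  expect_true(all(amp2[5:12]))

  amp3 <- vapply(1:12, function(cn) {
    classify_copy_number(seg(cn, 3.0), "PDGFRA", roles)$verdict == "driver"
  }, logical(1))
  expect_equal(min(which(amp3)), 9)      # >= 9 when ploidy >= 2.7
  expect_false(amp3[8])
})

test_that("TSG loss thresholds are exact, including the ploidy - 2.7 rule", {
  loss2 <- vapply(0:6, function(cn) {
    classify_copy_number(seg(cn, 2.0), "TP53", roles)$rationale == "tsg_loss"
  }, logical(1))
  expect_equal(which(loss2) - 1L, 0L)    # only CN 0 at diploid

  # CN 1 at ploidy 4.0: 1 <= 4.0 - 2.7, a loss; at ploidy 3.0: 1 > 0.3, not
  expect_equal(classify_copy_number(seg(1, 4.0), "TP53", roles)$verdict,
               "driver")
  expect_equal(classify_copy_number(seg(1, 3.0), "TP53", roles)$verdict,
               "not_driver")
  # boundary: ploidy exactly 2.7 uses the >= 2.7 arm
  expect_equal(classify_copy_number(seg(0, 2.7), "TP53", roles)$verdict,
               "driver")
})

test_that("copy-number tier rules respect width and fusion-only genes", {
  t1 <- classify_copy_number(seg(5, 2.0, width = 8e6), "PDGFRA", roles)
  expect_equal(t1$tier, "1")
  wide <- classify_copy_number(seg(5, 2.0, width = 12e6), "PDGFRA", roles)
  expect_equal(wide$verdict, "not_driver")
  narrow_t2 <- classify_copy_number(seg(5, 2.0, width = 5e5), "IDH1", roles)
  expect_equal(narrow_t2$tier, "2")
  # fusion-only gene: CN gain never tier 1, degrades to tier 2 if narrow
  ntrk <- classify_copy_number(seg(9, 3.0, width = 5e5), "NTRK1", roles)
  expect_equal(ntrk$tier, "2")
  ntrk_wide <- classify_copy_number(seg(9, 3.0, width = 5e6), "NTRK1", roles)
  expect_equal(ntrk_wide$verdict, "not_driver")
  expect_error(classify_copy_number(seg(-1, 2.0), "PDGFRA", roles), ">= 0")
})

test_that("structural-variant rules", {
  del <- classify_structural(list(type = "deletion",
                                  breakpoint_genes = c("NF1", "NF1")),
                             roles, fusions)
  expect_equal(del$verdict, "driver")
  expect_equal(del$rationale, "tsg_truncation")

  pdgfra <- classify_structural(list(type = "deletion",
                                     breakpoint_genes = c("PDGFRA", "PDGFRA")),
                                roles, fusions)
  expect_equal(pdgfra$rationale, "activating_intragenic_deletion")

  fus <- classify_structural(list(type = "translocation",
                                  breakpoint_genes = c("BRAF", "KIAA1549")),
                             roles, fusions)
  expect_equal(fus$rationale, "oncogenic_fusion")
  expect_equal(fus$tier, "1")

  none <- classify_structural(list(type = "inversion",
                                   breakpoint_genes = c(NA, NA)),
                              roles, fusions)
  expect_equal(none$verdict, "not_driver")

  # intragenic deletion of an oncogene without the activating mechanism
  kras <- classify_structural(list(type = "deletion",
                                   breakpoint_genes = c("KRAS", "KRAS")),
                              roles, fusions)
  expect_equal(kras$verdict, "not_driver")

  expect_error(classify_structural(list(type = "deletion",
                                        breakpoint_genes = c("NOPE", NA)),
                                   roles, fusions), "outside supplied")
})

test_that("verdicts are deterministic and carry exactly one rule id", {
  v <- list(gene = "NF1", consequence = "nonsense", residue = 304L)
  a <- classify_small_variant(v, roles, hotspots)
  b <- classify_small_variant(v, roles, hotspots)
  expect_identical(a, b)
  expect_length(a$rationale, 1L)
  expect_true(nzchar(a$rationale))
})

test_that("rules recover the simulator's planted drivers", {
  ch <- simulate_cohort(small_cohort_config(), seed = 8)
  pb <- ch$proband
  planted <- pb$clones[pb$clones$type == "point", ]
  for (i in seq_len(nrow(planted))) {
    call <- classify_small_variant(list(gene = pb$gene$gene_id,
                                        consequence = "nonsense",
                                        residue = 100L), roles, hotspots)
    expect_equal(call$verdict, "driver")
  }
  # passengers: a random synonymous change in the gene is never a driver
  pass <- classify_small_variant(list(gene = pb$gene$gene_id,
                                      consequence = "synonymous",
                                      residue = 10L), roles, hotspots)
  expect_equal(pass$verdict, "not_driver")
})
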
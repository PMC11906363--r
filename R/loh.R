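#' Null allele fraction of the tumor-retained haplotype
#'
#' In a sample with tumor contamination `purity` and otherwise diploid
#' heterozygous cells, the expected aggregate fraction of reads carrying the
#' tumor-retained haplotype's alleles is `purity + (1 - purity) * 0.5`: the
#' tumor compartment (LOH, retaining only that haplotype) contributes all its
#' reads, the normal compartment half. This is the success probability of
#' the exact binomial null used by [test_loh()].
#'
#' @param purity Tumor contamination fraction in `[0, 1]`.
#' @return Expected aggregate allele fraction under no somatic LOH.
#' @export
loh_null_p0 <- function(purity) {
  stopifnot(all(purity >= 0 & purity <= 1))
  purity + (1 - purity) * 0.5
}

#' Phase heterozygous SNPs using a tumor with chromosome-wide LOH
#'
#' For each heterozygous SNP, the allele with the greater allele fraction in
#' the (near-pure) tumor sample is marked as lying on the tumor-retained
#' haplotype -- the haplotype carrying the germline hit when the tumor lost
#' the wild-type allele. SNPs covered below `min_tumor_depth` and SNPs with
#' exactly tied allele fractions are dropped (and reported via attribute
#' `"dropped"`).
#'
#' @param het_snps data.frame of germline-heterozygous SNPs
#'   (`chrom, pos, ref, alt`; unique positions).
#' @param tumor_read_counts Read counts of the phasing tumor sample at those
#'   SNPs.
#' @param min_tumor_depth Minimum tumor depth for a SNP to be phased.
#' @return data.frame `chrom, pos, ref, alt, retained_is_alt`, with an
#'   integer attribute `"dropped"` (number of SNPs removed).
#' @export
phase_by_tumor <- function(het_snps, tumor_read_counts, min_tumor_depth = 10) {
  assert_columns(het_snps, c("chrom", "pos", "ref", "alt"), "het_snps")
  if (nrow(het_snps) == 0L) stop("empty SNP panel", call. = FALSE)
  if (anyDuplicated(site_key(het_snps$chrom, het_snps$pos, het_snps$ref,
                             het_snps$alt))) {
    stop("het_snps must have unique positions", call. = FALSE)
  }
  assert_columns(tumor_read_counts,
                 c("chrom", "pos", "ref", "alt", "depth", "alt_depth"),
                 "tumor_read_counts")
  idx <- match(site_key(het_snps$chrom, het_snps$pos, het_snps$ref,
                        het_snps$alt),
               site_key(tumor_read_counts$chrom, tumor_read_counts$pos,
                        tumor_read_counts$ref, tumor_read_counts$alt))
  depth <- tumor_read_counts$depth[idx]
  alt <- tumor_read_counts$alt_depth[idx]
  keep <- !is.na(depth) & depth >= min_tumor_depth & (2 * alt != depth)
  out <- het_snps[keep, c("chrom", "pos", "ref", "alt"), drop = FALSE]
  out$retained_is_alt <- alt[keep] > depth[keep] / 2
  rownames(out) <- NULL
  attr(out, "dropped") <- sum(!keep)
  out
}

#' Test samples for allelic imbalance at phased SNPs (LOH second hits)
#'
#' Per sample: keep phased SNPs covered at `>= min_site_depth` in that
#' sample; sum total coverage over kept SNPs (trials) and coverage of the
#' tumor-retained alleles (successes); perform a two-sided exact binomial
#' test against the purity-adjusted null `p0 = purity + (1 - purity) * 0.5`.
#' P values are Benjamini--Hochberg adjusted across all samples tested in
#' the run. A sample is flagged as carrying an LOH clone only when
#' `q < q_threshold`, its median kept-SNP coverage is at least
#' `min_median_coverage`, and its tumor contamination is below `max_purity`
#' -- so that imbalance cannot be explained by tumor infiltration.
#'
#' Direction is `wt_loss` when the retained (mutant) haplotype is in excess
#' and `mutant_loss` when the wild-type haplotype is favored. Because the
#' mechanism behind an imbalance is not identifiable from aggregate counts,
#' the implied clone fraction is reported under both models: copy-neutral
#' LOH (`clone_fraction_cnloh = 2 a - 1`) and one-copy deletion
#' (`clone_fraction_deletion = (2 a - 1) / a`), where `a` is the aggregate
#' fraction of the favored haplotype at zero purity.
#'
#' @param read_counts Multi-sample read-count table covering the phased SNPs.
#' @param phased_snps Output of [phase_by_tumor()].
#' @param purities Named numeric vector (or data.frame `sample_id, purity`)
#'   of tumor-contamination estimates; samples without an entry get purity 0
#'   with a warning.
#' @param min_site_depth Per-SNP coverage floor (reads).
#' @param q_threshold BH-adjusted significance gate.
#' @param min_median_coverage Median kept-SNP coverage gate (reads).
#' @param max_purity Purity gate (fraction); imbalance in samples at or
#'   above it is attributed to tumor contamination.
#' @return data.frame with one row per sample: `sample_id, n_snps_used,
#'   trials, successes, p0, aggregate_fraction, p_value, q_value, flagged,
#'   direction, clone_fraction_cnloh, clone_fraction_deletion, testable`.
#' @export
test_loh <- function(read_counts, phased_snps, purities,
                     min_site_depth = 10, q_threshold = 0.01,
                     min_median_coverage = 30, max_purity = 0.01) {
  if (nrow(phased_snps) == 0L) stop("empty phased-SNP panel", call. = FALSE)
  assert_columns(phased_snps,
                 c("chrom", "pos", "ref", "alt", "retained_is_alt"),
                 "phased_snps")
  if (is.data.frame(purities)) {
    purities <- stats::setNames(purities$purity, purities$sample_id)
  }
  panel_key <- site_key(phased_snps$chrom, phased_snps$pos, phased_snps$ref,
                        phased_snps$alt)
  per_sample <- lapply(split(read_counts, read_counts$sample_id),
                       function(rc) {
    idx <- match(panel_key, site_key(rc$chrom, rc$pos, rc$ref, rc$alt))
    depth <- rc$depth[idx]
    altd <- rc$alt_depth[idx]
    keep <- !is.na(depth) & depth >= min_site_depth
    sid <- rc$sample_id[1]
    purity <- if (sid %in% names(purities)) unname(purities[sid]) else {
      warning(sprintf("no purity estimate for sample %s; assuming 0", sid))
      0
    }
    if (!any(keep)) {
      return(data.frame(sample_id = sid, n_snps_used = 0L, trials = 0L,
                        successes = 0L, p0 = loh_null_p0(purity),
                        aggregate_fraction = NA_real_, p_value = NA_real_,
                        testable = FALSE, purity = purity,
                        median_coverage = NA_real_, stringsAsFactors = FALSE))
    }
    retained_depth <- ifelse(phased_snps$retained_is_alt[keep], altd[keep],
                             depth[keep] - altd[keep])
    trials <- sum(depth[keep])
    successes <- sum(retained_depth)
    p0 <- loh_null_p0(purity)
    p <- stats::binom.test(successes, trials, p0,
                           alternative = "two.sided")$p.value
    data.frame(sample_id = sid, n_snps_used = sum(keep), trials = trials,
               successes = successes, p0 = p0,
               aggregate_fraction = successes / trials, p_value = p,
               testable = TRUE, purity = purity,
               median_coverage = stats::median(depth[keep]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_sample)
  rownames(out) <- NULL
  out$q_value <- NA_real_
  tested <- out$testable
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$flagged <- tested &
    !is.na(out$q_value) & out$q_value < q_threshold &
    out$median_coverage >= min_median_coverage &
    out$purity < max_purity
  a <- out$aggregate_fraction
  out$direction <- ifelse(!tested | a == out$p0, "none",
                          ifelse(a > out$p0, "wt_loss", "mutant_loss"))
  # clone fractions from the favored haplotype's aggregate fraction
  af <- pmax(a, 1 - a)
  out$clone_fraction_cnloh <- ifelse(tested, 2 * af - 1, NA_real_)
  out$clone_fraction_deletion <- ifelse(tested, (2 * af - 1) / af, NA_real_)
  out
}
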
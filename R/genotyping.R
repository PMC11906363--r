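#' One-sided Fisher exact p for enrichment of alt reads over a pooled panel
#'
#' Exact one-sided Fisher p value for the 2x2 table
#' `[[alt_case, depth_case - alt_case], [alt_ctrl, depth_ctrl - alt_ctrl]]`,
#' testing enrichment of alt reads in the case sample. Computed as the
#' hypergeometric upper tail, which is the one-sided Fisher test; vectorized
#' over sites/samples.
#'
#' @param alt_case,depth_case Case alt and total read counts.
#' @param alt_ctrl,depth_ctrl Pooled-control alt and total read counts.
#' @return Numeric vector of p values.
#' @export
fisher_presence_p <- function(alt_case, depth_case, alt_ctrl, depth_ctrl) {
  stopifnot(all(alt_case <= depth_case), all(alt_ctrl <= depth_ctrl))
  stats::phyper(alt_case - 1, alt_case + alt_ctrl,
                (depth_case - alt_case) + (depth_ctrl - alt_ctrl),
                depth_case, lower.tail = FALSE)
}

#' Genotype candidate mutations against a pooled error panel
#'
#' For each (mutation, sample) pair, tests whether the sample's variant read
#' support exceeds what the locus-specific sequencing error rate -- estimated
#' by pooling read counts at the same site across control samples -- can
#' explain, using a one-sided Fisher's exact test on the summed variant and
#' total read depths. P values are Benjamini--Hochberg adjusted over all
#' (mutation x sample) tests in the run and a mutation is declared present
#' when `q < q_threshold` (and, optionally, at least `min_alt` supporting
#' reads are seen).
#'
#' @param mutation_sites data.frame of candidate mutations
#'   (`chrom, pos, ref, alt`, optionally `mutation_id`).
#' @param case_counts Read-count table of the samples to genotype.
#' @param control_counts Read-count table of the control pool; counts are
#'   summed per site across its samples.
#' @param q_threshold BH-adjusted significance gate for presence.
#' @param min_alt Minimum alt reads in the case sample (default 0: the exact
#'   test alone decides).
#' @return data.frame with one row per (mutation, sample): `mutation_id,
#'   sample_id, chrom, pos, ref, alt, alt_depth, depth, control_alt_sum,
#'   control_depth_sum, p_value, q_value, present`. Pairs with zero case
#'   depth are reported untested (`p_value = NA`, `present = FALSE`).
#' @export
genotype_presence <- function(mutation_sites, case_counts, control_counts,
                              q_threshold = 0.01, min_alt = 0L) {
  assert_columns(mutation_sites, c("chrom", "pos", "ref", "alt"),
                 "mutation_sites")
  assert_columns(case_counts, c("sample_id", "chrom", "pos", "ref", "alt",
                                "depth", "alt_depth"), "case_counts")
  assert_columns(control_counts, c("chrom", "pos", "ref", "alt",
                                   "depth", "alt_depth"), "control_counts")
  mut_key <- site_key(mutation_sites$chrom, mutation_sites$pos,
                      mutation_sites$ref, mutation_sites$alt)
  if (!"mutation_id" %in% names(mutation_sites)) {
    mutation_sites$mutation_id <- mut_key
  }

  ctl_key <- site_key(control_counts$chrom, control_counts$pos,
                      control_counts$ref, control_counts$alt)
  ctl_idx <- match(ctl_key, mut_key)
  in_panel <- !is.na(ctl_idx)
  f <- factor(ctl_idx[in_panel], levels = seq_along(mut_key))
  ctl_alt <- as.numeric(tapply(control_counts$alt_depth[in_panel], f, sum,
                               default = 0))
  ctl_depth <- as.numeric(tapply(control_counts$depth[in_panel], f, sum,
                                 default = 0))
  if (any(ctl_depth == 0)) {
    stop("control pool has zero depth at one or more candidate sites",
         call. = FALSE)
  }

  case_key <- site_key(case_counts$chrom, case_counts$pos, case_counts$ref,
                       case_counts$alt)
  case_idx <- match(case_key, mut_key)
  cc <- case_counts[!is.na(case_idx), , drop = FALSE]
  mi <- case_idx[!is.na(case_idx)]
  out <- data.frame(
    mutation_id = mutation_sites$mutation_id[mi],
    sample_id = cc$sample_id,
    chrom = cc$chrom, pos = cc$pos, ref = cc$ref, alt = cc$alt,
    alt_depth = cc$alt_depth, depth = cc$depth,
    control_alt_sum = ctl_alt[mi], control_depth_sum = ctl_depth[mi],
    stringsAsFactors = FALSE)
  out$p_value <- ifelse(out$depth > 0,
                        fisher_presence_p(out$alt_depth, out$depth,
                                          out$control_alt_sum,
                                          out$control_depth_sum),
                        NA_real_)
  out$q_value <- NA_real_
  tested <- !is.na(out$p_value)
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$present <- tested & !is.na(out$q_value) & out$q_value < q_threshold &
    out$alt_depth >= min_alt
  out
}

#' Shearwater-like presence matrix with a leave-one-out sample panel
#'
#' Runs the pooled-Fisher presence test of [genotype_presence()] for every
#' sample at every candidate site, but with the error panel built from all
#' *other* samples in the table (leave-one-out) instead of separate control
#' individuals. This is the simplified site-specific error-model caller used
#' to decide whether a substitution is shared between two tissues; a
#' `min_alt` floor of 2 supporting reads is applied by default.
#'
#' @inheritParams genotype_presence
#' @param read_counts Multi-sample read-count table (>= 2 samples).
#' @return As [genotype_presence()].
#' @export
presence_by_panel <- function(mutation_sites, read_counts,
                              q_threshold = 0.01, min_alt = 2L) {
  samples <- unique(read_counts$sample_id)
  if (length(samples) < 2L) {
    stop("leave-one-out panel needs at least 2 samples", call. = FALSE)
  }
  res <- lapply(samples, function(s) {
    g <- genotype_presence(mutation_sites,
                           read_counts[read_counts$sample_id == s, ],
                           read_counts[read_counts$sample_id != s, ],
                           q_threshold = 1, min_alt = 0L)
    g
  })
  out <- do.call(rbind, res)
  # one BH family across all (mutation x sample) tests in the run
  tested <- !is.na(out$p_value)
  out$q_value <- NA_real_
  out$q_value[tested] <- stats::p.adjust(out$p_value[tested], method = "BH")
  out$present <- tested & !is.na(out$q_value) & out$q_value < q_threshold &
    out$alt_depth >= min_alt
  out
}
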
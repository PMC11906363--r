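#' False-presence rate of the pooled-control genotyper under a global null
#'
#' Simulates replicates in which no sample carries any candidate mutation:
#' case and control read counts at every site are pure sequencing error with
#' a shared (matched) per-site alt-read rate. Each replicate runs
#' [genotype_presence()] with Benjamini--Hochberg correction over all
#' (mutation x sample) tests and records whether any call was made. With a
#' correctly matched error model the fraction of replicates with at least
#' one false "present" call is bounded by the q threshold.
#'
#' @param n_reps Number of replicates.
#' @param n_samples Case samples per replicate.
#' @param n_sites Candidate mutation sites per replicate.
#' @param depth Case read depth per site.
#' @param error_rate Per-site alt-read error probability (shared by case and
#'   control pools).
#' @param control_depth_total Pooled control depth per site.
#' @param q_threshold BH presence gate.
#' @param seed Integer seed.
#' @return List: `false_rate` (fraction of replicates with any call),
#'   `n_reps`, `n_tests_per_rep`.
#' @export
null_false_presence_rate <- function(n_reps = 500, n_samples = 200,
                                     n_sites = 3, depth = 40,
                                     error_rate = 1e-3,
                                     control_depth_total = 8000,
                                     q_threshold = 0.01, seed = 1L) {
  set.seed(derive_seed(seed, "null_genotyping"))
  sites <- data.frame(mutation_id = paste0("m", seq_len(n_sites)),
                      chrom = "17", pos = seq_len(n_sites), ref = "G",
                      alt = "A", stringsAsFactors = FALSE)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  case_tpl <- data.frame(sample_id = rep(sample_ids, each = n_sites),
                         chrom = "17", pos = rep(seq_len(n_sites), n_samples),
                         ref = "G", alt = "A", depth = depth,
                         stringsAsFactors = FALSE)
  any_present <- vapply(seq_len(n_reps), function(i) {
    case <- case_tpl
    case$alt_depth <- stats::rbinom(nrow(case), depth, error_rate)
    ctl <- data.frame(chrom = "17", pos = seq_len(n_sites), ref = "G",
                      alt = "A", depth = control_depth_total,
                      alt_depth = stats::rbinom(n_sites, control_depth_total,
                                                error_rate),
                      stringsAsFactors = FALSE)
    g <- genotype_presence(sites, case, ctl, q_threshold = q_threshold)
    any(g$present)
  }, logical(1))
  list(false_rate = mean(any_present), n_reps = n_reps,
       n_tests_per_rep = n_samples * n_sites)
}

#' False-flag rate of the LOH caller under a no-LOH null
#'
#' Simulates replicates of LOH-free samples with correctly specified purity:
#' per phased SNP, depth is Poisson and retained-allele reads are binomial at
#' the null fraction `p0 = purity + (1 - purity) * 0.5`. Each replicate runs
#' [test_loh()] with BH correction and the coverage/purity gates and records
#' whether any sample was flagged.
#'
#' @param n_reps Number of replicates.
#' @param n_samples Samples per replicate.
#' @param n_snps Phased SNPs per sample.
#' @param depth Mean per-SNP coverage (Poisson).
#' @param purity True (and supplied) tumor contamination of every sample.
#' @param q_threshold BH flag gate.
#' @param seed Integer seed.
#' @return List: `flag_rate`, `n_reps`, `n_samples`.
#' @export
null_loh_flag_rate <- function(n_reps = 500, n_samples = 100, n_snps = 1000,
                               depth = 40, purity = 0, q_threshold = 0.01,
                               seed = 1L) {
  set.seed(derive_seed(seed, "null_loh"))
  snps <- data.frame(chrom = "17", pos = seq_len(n_snps), ref = "A",
                     alt = "C",
                     retained_is_alt = rep(c(TRUE, FALSE),
                                           length.out = n_snps),
                     stringsAsFactors = FALSE)
  sample_ids <- sprintf("s%03d", seq_len(n_samples))
  purities <- stats::setNames(rep(purity, n_samples), sample_ids)
  p0 <- loh_null_p0(purity)
  n <- n_samples * n_snps
  tpl <- data.frame(sample_id = rep(sample_ids, each = n_snps),
                    chrom = "17", pos = rep(seq_len(n_snps), n_samples),
                    ref = "A", alt = "C", stringsAsFactors = FALSE)
  p_alt <- rep(ifelse(snps$retained_is_alt, p0, 1 - p0), n_samples)
  any_flag <- vapply(seq_len(n_reps), function(i) {
    rc <- tpl
    rc$depth <- stats::rpois(n, depth)
    rc$alt_depth <- stats::rbinom(n, rc$depth, p_alt)
    res <- test_loh(rc, snps, purities, q_threshold = q_threshold)
    any(res$flagged)
  }, logical(1))
  list(flag_rate = mean(any_flag), n_reps = n_reps, n_samples = n_samples)
}

#' Cohort configuration with a recent shared ancestor carrying a second hit
#'
#' Two samples descend from an ancestor two branches (about
#' `2 * branch_mutation_rate` substitutions) below the root that carries a
#' truncating point second hit; control samples hang directly off the root,
#' so control pairs share no somatic mutations beyond noise.
#'
#' @param n_controls Number of control (unrelated) samples.
#' @param branch_mutation_rate Substitutions per branch (Poisson mean).
#' @param depth Sequencing depth of every sample.
#' @return A cohort configuration for [simulate_cohort()].
#' @export
related_pair_config <- function(n_controls = 10, branch_mutation_rate = 150,
                                depth = 40) {
  cfg <- default_cohort_config()
  cfg$branch_mutation_rate <- branch_mutation_rate
  n_ctl_nodes <- n_controls
  # nodes: 1 root, 2-3 chained ancestors, 4-5 related samples,
  # 6..(5+n) control clades, last node the tumor
  parents <- c(NA, 1, 2, 3, 3, rep(1L, n_ctl_nodes), 1)
  tumor_node <- length(parents)
  mk <- function(id, node) {
    list(sample_id = id, modality = "lcm",
         clone_fractions = stats::setNames(0.95, as.character(node)),
         tumor_contamination = 0, target_depth = depth, error_rate = 1e-3,
         stratum = "CNS", tissue_piece_id = id)
  }
  cfg$proband$parents <- parents
  cfg$proband$tumor <- list(node = tumor_node, mechanism = "cnloh",
                            lost = "wt")
  cfg$proband$clones <- list(list(id = "shared_hit", node = 2,
                                  type = "point"))
  cfg$proband$samples <- c(
    list(mk("REL_A", 4), mk("REL_B", 5)),
    lapply(seq_len(n_ctl_nodes), function(i) {
      mk(sprintf("CTL_%02d", i), 5 + i)
    }))
  cfg
}

#' Permutation P value for a simulated related pair
#'
#' End-to-end run of the shared-ancestry analysis on [related_pair_config()]:
#' read counts are emitted for every sample at all somatic candidate sites,
#' presence is called against the control individuals' pooled error panel,
#' pairwise shared-substitution counts are computed, and the related pair's
#' mean is compared with draws from the unrelated-pair pool.
#'
#' @param seed Integer seed.
#' @param n_draws Permutation draws.
#' @param config Cohort configuration (defaults to [related_pair_config()]).
#' @return The [permutation_test()] result, with the sharing table attached
#'   as attribute `"sharing"`.
#' @export
related_ancestry_pvalue <- function(seed = 1L, n_draws = 1000,
                                    config = related_pair_config()) {
  ch <- simulate_cohort(config, seed)
  pb <- ch$proband
  somatic <- mutation_sites(pb)
  somatic <- somatic[!(somatic$mutation_id %in% truncal_mutations(pb)), ]
  sites <- somatic[, c("chrom", "pos", "ref", "alt")]
  rc <- emit_all_read_counts(pb, sites, derive_seed(seed, "rel_reads"))
  ctl_rc <- do.call(rbind, lapply(ch[-1], function(ctl) {
    emit_all_read_counts(ctl, sites,
                         derive_seed(seed, paste0("rel_ctl_", ctl$id)))
  }))
  presence <- genotype_presence(somatic, rc, ctl_rc, min_alt = 2)
  ids <- vapply(pb$samples, `[[`, character(1), "sample_id")
  test <- pairwise_sharing(presence, ids[startsWith(ids, "REL_")],
                           group = "test")
  ctl <- pairwise_sharing(presence, ids[startsWith(ids, "CTL_")],
                          group = "control")
  res <- permutation_test(test$shared_count, ctl$shared_count,
                          n_draws = n_draws,
                          seed = derive_seed(seed, "rel_perm"))
  attr(res, "sharing") <- rbind(test, ctl)
  res
}

#' Copy-number thresholds implied by the driver rules
#'
#' Scans integer total copy numbers and reports which are classified as
#' oncogene amplification (or tumor-suppressor loss) at the given ploidy.
#'
#' @param ploidy Sample ploidy.
#' @param role `"oncogene"` (amplification scan) or `"tsg"` (loss scan).
#' @param cn_values Integer copy numbers to scan.
#' @param width Segment width in bp (defaults inside the tier-1 window).
#' @return Integer vector of copy numbers classified as driver events.
#' @export
cn_driver_values <- function(ploidy, role = c("oncogene", "tsg"),
                             cn_values = NULL, width = 8e6) {
  role <- match.arg(role)
  cn_values <- cn_values %||% if (role == "oncogene") 1:12 else 0:6
  gene <- if (role == "oncogene") "PDGFRA" else "TP53"
  hits <- vapply(cn_values, function(cn) {
    seg <- list(chrom = "4", start = 1e6, end = 1e6 + width - 1,
                total_cn = cn, sample_ploidy = ploidy)
    classify_copy_number(seg, gene)$verdict == "driver"
  }, logical(1))
  cn_values[hits]
}
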
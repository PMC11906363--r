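#' Estimate tumor contamination of a sample from truncal mutations
#'
#' Truncal mutations are present in every tumor cell; at a
#' diploid-heterozygous truncal site, contaminating tumor cells at fraction
#' `t` contribute an expected allele fraction of `t / 2`. Pooling read counts
#' over all truncal sites, the estimator is `purity = min(1, 2 * sum(alt) /
#' sum(depth))`, with a 95\% confidence interval obtained by exact
#' (Clopper--Pearson) binomial limits on the pooled counts mapped through the
#' same doubling. Pooling (rather than per-site summaries) maximizes
#' sensitivity at sub-percent contamination, which is the gate the LOH caller
#' applies. Truncal sites on segments the tumor holds in LOH are excluded by
#' the caller upstream (the doubling is exact only at diploid-het sites).
#'
#' @param truncal_sites data.frame of truncal mutation sites with columns
#'   `chrom, pos, ref, alt` (a `mutation_id` column is carried if present).
#' @param read_counts Read-count table for one sample (`sample_id, chrom,
#'   pos, ref, alt, depth, alt_depth`); rows are matched to `truncal_sites`
#'   by site, other rows are ignored.
#' @param conf_level Confidence level for the interval.
#' @return One-row data.frame: `sample_id, purity, ci_low, ci_high, n_sites,
#'   total_depth, total_alt`.
#' @export
estimate_purity <- function(truncal_sites, read_counts, conf_level = 0.95) {
  assert_columns(truncal_sites, c("chrom", "pos", "ref", "alt"),
                 "truncal_sites")
  assert_columns(read_counts,
                 c("sample_id", "chrom", "pos", "ref", "alt",
                   "depth", "alt_depth"), "read_counts")
  if (nrow(truncal_sites) == 0L) {
    stop("truncal site set is empty", call. = FALSE)
  }
  sid <- unique(read_counts$sample_id)
  if (length(sid) != 1L) {
    stop("read_counts must contain exactly one sample; use estimate_purity_all()",
         call. = FALSE)
  }
  keep <- site_key(read_counts$chrom, read_counts$pos, read_counts$ref,
                   read_counts$alt) %in%
    site_key(truncal_sites$chrom, truncal_sites$pos, truncal_sites$ref,
             truncal_sites$alt)
  rc <- read_counts[keep, , drop = FALSE]
  total_depth <- sum(rc$depth)
  total_alt <- sum(rc$alt_depth)
  if (nrow(rc) == 0L || total_depth == 0L) {
    stop("no truncal site with nonzero depth: purity undefined", call. = FALSE)
  }
  bt <- stats::binom.test(total_alt, total_depth, conf.level = conf_level)
  data.frame(
    sample_id = sid,
    purity = min(1, 2 * total_alt / total_depth),
    ci_low = min(1, 2 * bt$conf.int[1]),
    ci_high = min(1, 2 * bt$conf.int[2]),
    n_sites = nrow(rc), total_depth = total_depth, total_alt = total_alt,
    stringsAsFactors = FALSE)
}

#' Estimate tumor contamination for every sample in a read-count table
#'
#' @inheritParams estimate_purity
#' @param read_counts Multi-sample read-count table.
#' @return data.frame with one row per sample (see [estimate_purity()]).
#' @export
estimate_purity_all <- function(truncal_sites, read_counts,
                                conf_level = 0.95) {
  do.call(rbind, lapply(split(read_counts, read_counts$sample_id),
                        function(rc) {
                          estimate_purity(truncal_sites, rc, conf_level)
                        })) |>
    (\(d) { rownames(d) <- NULL; d })()
}
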
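#' Count substitutions shared by two samples
#'
#' A substitution is shared when the presence caller declares it present in
#' both samples. Germline variants must be excluded upstream (the candidate
#' set is somatic).
#'
#' @param presence Presence table (output of [presence_by_panel()] or
#'   [genotype_presence()]) covering both samples.
#' @param sample_a,sample_b Sample ids.
#' @return Integer count of substitutions present in both.
#' @export
count_shared_substitutions <- function(presence, sample_a, sample_b) {
  pa <- presence[presence$sample_id == sample_a & presence$present, ]
  pb <- presence[presence$sample_id == sample_b & presence$present, ]
  if (nrow(presence[presence$sample_id == sample_a, ]) == 0L ||
      nrow(presence[presence$sample_id == sample_b, ]) == 0L) {
    warning("no covered sites for one of the samples; shared count is 0")
    return(0L)
  }
  length(intersect(pa$mutation_id, pb$mutation_id))
}

#' Pairwise shared-substitution counts for a set of samples
#'
#' @param presence Presence table covering the samples.
#' @param samples Character vector of sample ids (all unordered pairs are
#'   compared).
#' @param group Label stored in the `group` column.
#' @return data.frame `sample_a, sample_b, shared_count, group`.
#' @export
pairwise_sharing <- function(presence, samples, group = "control") {
  if (length(samples) < 2L) {
    stop("need at least two samples for pairwise comparison", call. = FALSE)
  }
  pairs <- utils::combn(samples, 2)
  data.frame(
    sample_a = pairs[1, ], sample_b = pairs[2, ],
    shared_count = apply(pairs, 2, function(p) {
      count_shared_substitutions(presence, p[1], p[2])
    }),
    group = group, stringsAsFactors = FALSE)
}

#' Permutation test for excess mutation sharing
#'
#' Tests whether tissue pairs carrying the same second hit share more
#' genome-wide substitutions than random pairs of unrelated normal tissues.
#' The statistic is the mean shared-substitution count over the test pairs.
#' For each of `n_draws` repetitions, the same number of counts is drawn from
#' the control pool at random without replacement and its mean recorded; the
#' one-sided P value is the fraction of draws whose control mean is strictly
#' greater than the test mean (ties count as non-exceedances). When no draw
#' exceeds, the result is displayed as a bound (`"<1/n_draws"`) and stored
#' as 0.
#'
#' @param test_counts Shared-substitution counts of the test pairs.
#' @param control_pool Shared-substitution counts of control pairs (length
#'   >= `length(test_counts)`).
#' @param n_draws Number of random draws.
#' @param seed Integer seed.
#' @return List of class `sh_permutation`: `test_mean, n_test_pairs, n_draws,
#'   exceed_count, p_value, p_display`.
#' @export
permutation_test <- function(test_counts, control_pool, n_draws = 1000,
                             seed = 1L) {
  if (length(test_counts) == 0L) stop("empty test set", call. = FALSE)
  k <- length(test_counts)
  if (length(control_pool) < k) {
    stop("control pool smaller than the number of test pairs", call. = FALSE)
  }
  test_mean <- mean(test_counts)
  set.seed(seed)
  draw_means <- vapply(seq_len(n_draws), function(i) {
    mean(sample(control_pool, k, replace = FALSE))
  }, numeric(1))
  exceed <- sum(draw_means > test_mean)
  structure(
    list(test_mean = test_mean, n_test_pairs = k, n_draws = n_draws,
         exceed_count = exceed, p_value = exceed / n_draws,
         p_display = if (exceed == 0) sprintf("<%g", 1 / n_draws)
                     else format(exceed / n_draws)),
    class = "sh_permutation")
}

#' @export
print.sh_permutation <- function(x, ...) {
  cat(sprintf(
    "<permutation test> mean shared = %.2f over %d pair(s); P %s (%d/%d draws exceeded)\n",
    x$test_mean, x$n_test_pairs,
    if (x$exceed_count == 0) x$p_display else paste("=", x$p_display),
    x$exceed_count, x$n_draws))
  invisible(x)
}

#' Exact permutation P by exhaustive enumeration
#'
#' Enumerates every subset of the control pool of the test-pair size and
#' returns the exact fraction whose mean strictly exceeds the test mean.
#' Used as the reference for [permutation_test()] on small pools.
#'
#' @inheritParams permutation_test
#' @return Exact P value.
#' @export
permutation_test_exact <- function(test_counts, control_pool) {
  k <- length(test_counts)
  test_mean <- mean(test_counts)
  combos <- utils::combn(length(control_pool), k)
  means <- apply(combos, 2, function(idx) mean(control_pool[idx]))
  sum(means > test_mean) / ncol(combos)
}
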
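#' Call variants from duplex read bundles
#'
#' A duplex call requires concordant support from both strands of at least
#' one molecule: per strand, the consensus is a simple majority of that
#' strand's reads (ties give no consensus) and at least `min_reads_per_strand`
#' variant reads; a molecule supports the variant when both of its strand
#' consensuses do. Sites present in the matched-normal call set are excluded
#' (germline). Duplex coverage at a site counts molecules with reads on both
#' strands, irrespective of variant content.
#'
#' @param bundles Duplex bundle table (`molecule_id, sample_id, chrom, pos,
#'   ref, alt, strand, reads, variant_reads`); at most one row per
#'   (molecule, strand, site).
#' @param matched_normal_calls data.frame of sites called in the matched
#'   normal (`chrom, pos, ref, alt`), or `NULL`.
#' @param min_reads_per_strand Minimum variant reads per strand.
#' @return data.frame with one row per (sample, site): `sample_id, chrom,
#'   pos, ref, alt, n_duplex_support, duplex_coverage, in_normal, called`.
#' @export
call_duplex <- function(bundles, matched_normal_calls = NULL,
                        min_reads_per_strand = 1L) {
  assert_columns(bundles, c("molecule_id", "sample_id", "chrom", "pos",
                            "ref", "alt", "strand", "reads",
                            "variant_reads"), "bundles")
  if (any(bundles$variant_reads > bundles$reads)) {
    stop("variant_reads exceeds reads in one or more bundle rows",
         call. = FALSE)
  }
  if (!all(bundles$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'", call. = FALSE)
  }
  mol_key <- paste(bundles$sample_id, bundles$molecule_id,
                   site_key(bundles$chrom, bundles$pos, bundles$ref,
                            bundles$alt), sep = "\r")
  if (anyDuplicated(paste(mol_key, bundles$strand))) {
    stop("inconsistent bundle: multiple rows for one (molecule, strand, site)",
         call. = FALSE)
  }

  supports <- bundles$variant_reads >= min_reads_per_strand &
    2L * bundles$variant_reads > bundles$reads
  covered <- bundles$reads > 0L

  f <- factor(mol_key)
  n_strands <- tapply(covered, f, sum, default = 0)
  n_support <- tapply(supports, f, sum, default = 0)
  first <- match(levels(f), mol_key)

  per_mol <- data.frame(
    sample_id = bundles$sample_id[first],
    chrom = bundles$chrom[first], pos = bundles$pos[first],
    ref = bundles$ref[first], alt = bundles$alt[first],
    both_covered = as.integer(n_strands) == 2L,
    both_support = as.integer(n_support) == 2L,
    stringsAsFactors = FALSE)

  sk <- paste(per_mol$sample_id,
              site_key(per_mol$chrom, per_mol$pos, per_mol$ref, per_mol$alt),
              sep = "\r")
  g <- factor(sk)
  firsts <- match(levels(g), sk)
  out <- data.frame(
    sample_id = per_mol$sample_id[firsts],
    chrom = per_mol$chrom[firsts], pos = per_mol$pos[firsts],
    ref = per_mol$ref[firsts], alt = per_mol$alt[firsts],
    n_duplex_support = as.integer(tapply(per_mol$both_support &
                                           per_mol$both_covered, g, sum,
                                         default = 0)),
    duplex_coverage = as.integer(tapply(per_mol$both_covered, g, sum,
                                        default = 0)),
    stringsAsFactors = FALSE)
  out$in_normal <- if (is.null(matched_normal_calls) ||
                       nrow(matched_normal_calls) == 0L) {
    FALSE
  } else {
    site_key(out$chrom, out$pos, out$ref, out$alt) %in%
      site_key(matched_normal_calls$chrom, matched_normal_calls$pos,
               matched_normal_calls$ref, matched_normal_calls$alt)
  }
  out$called <- out$n_duplex_support >= 1L & !out$in_normal
  rownames(out) <- NULL
  out[order(out$sample_id, out$chrom, out$pos), , drop = FALSE]
}
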
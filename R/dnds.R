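#' Construct a gene model
#'
#' Holds the coding sequence in translation order, the exon structure that
#' projects it onto the genome, and the set of essential splice-site
#' positions (by default the two intronic bases flanking each exon
#' boundary, whose disruption is treated as truncating).
#'
#' @param gene_id Gene symbol.
#' @param cds_sequence Coding sequence (character, translation order, length
#'   divisible by 3, ACGT alphabet).
#' @param exons data.frame of `chrom, start, end` (1-based, closed),
#'   ordered by genomic position; widths must sum to `nchar(cds_sequence)`.
#' @param strand `"+"` or `"-"`. On the minus strand the CDS runs over the
#'   exons in reverse genomic order and genome-space alleles are the
#'   complements of CDS-space alleles.
#' @param splice_site_positions Genomic positions classified as essential
#'   splice sites; `NULL` derives donor/acceptor +-2 positions from the
#'   intron boundaries.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, cds_sequence, exons, strand = "+",
                       splice_site_positions = NULL) {
  cds_sequence <- toupper(cds_sequence)
  n <- nchar(cds_sequence)
  if (n %% 3 != 0) stop("CDS length must be divisible by 3", call. = FALSE)
  if (grepl("[^ACGT]", cds_sequence)) {
    stop("CDS may only contain A/C/G/T", call. = FALSE)
  }
  assert_columns(exons, c("chrom", "start", "end"), "exons")
  if (length(unique(exons$chrom)) != 1L) {
    stop("all exons must be on one chromosome", call. = FALSE)
  }
  widths <- exons$end - exons$start + 1
  if (any(widths < 1) || sum(widths) != n) {
    stop("exon widths must be positive and sum to the CDS length",
         call. = FALSE)
  }
  if (is.null(splice_site_positions) && nrow(exons) > 1L) {
    sp <- integer(0)
    for (i in seq_len(nrow(exons) - 1L)) {
      sp <- c(sp, exons$end[i] + 1:2, exons$start[i + 1] - 2:1)
    }
    splice_site_positions <- sort(unique(sp))
  }
  # genomic position of each CDS base, in translation order
  gpos <- unlist(lapply(seq_len(nrow(exons)),
                        function(i) exons$start[i]:exons$end[i]))
  if (strand == "-") gpos <- rev(gpos)
  structure(
    list(gene_id = gene_id, strand = strand, exons = exons,
         cds_sequence = cds_sequence,
         splice_site_positions = splice_site_positions %||% integer(0),
         chrom = exons$chrom[1], cds_genomic_pos = gpos),
    class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s strand): %d bp CDS over %d exon(s), %d splice positions\n",
              x$gene_id, x$strand, nchar(x$cds_sequence), nrow(x$exons),
              length(x$splice_site_positions)))
  invisible(x)
}

#' Random gene model for simulations
#'
#' CDS assembled from sense codons only (no internal stops), split over a
#' configurable number of exons.
#'
#' @param n_codons Number of codons.
#' @param seed Integer seed.
#' @param gene_id Gene symbol.
#' @param chrom,start Genomic placement of the first exon.
#' @param n_exons Number of exons.
#' @param intron_length Length of each intron.
#' @return A `gene_model`.
#' @export
random_gene_model <- function(n_codons, seed, gene_id = "GENE",
                              chrom = "17", start = 31094927L,
                              n_exons = 3L, intron_length = 500L) {
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  cds <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
  n <- nchar(cds)
  n_exons <- min(n_exons, n)
  cuts <- sort(c(0, sample(seq_len(n - 1), n_exons - 1), n))
  widths <- diff(cuts)
  starts <- integer(n_exons)
  ends <- integer(n_exons)
  s <- start
  for (i in seq_len(n_exons)) {
    starts[i] <- s
    ends[i] <- s + widths[i] - 1L
    s <- ends[i] + intron_length + 1L
  }
  gene_model(gene_id, cds,
             data.frame(chrom = chrom, start = starts, end = ends,
                        stringsAsFactors = FALSE))
}

complement_base <- function(b) {
  chartr("ACGT", "TGCA", b)
}

#' Enumerate the impact of every possible CDS substitution
#'
#' Lists all three alternative alleles at every CDS position, classified by
#' codon translation (standard genetic code) into synonymous, missense or
#' nonsense; positions in the essential splice-site set are classified as
#' `splice` and count as truncating, and intronic splice positions are
#' appended with `cds_pos = NA`. The trinucleotide context is taken from the
#' CDS itself (`N`-padded at the gene ends and unknown, `NNN`, for intronic
#' splice rows).
#'
#' @param gm A [gene_model()].
#' @return data.frame with `cds_pos, genomic_pos, ref, alt, ref_genome,
#'   alt_genome, impact, trinucleotide_context, codon_index`; `impact` is one
#'   of `synonymous, missense, nonsense, splice`.
#' @export
enumerate_impacts <- function(gm) {
  gc_tab <- Biostrings::GENETIC_CODE
  cds <- strsplit(gm$cds_sequence, "")[[1]]
  n <- length(cds)
  bases <- c("A", "C", "G", "T")

  cds_pos <- rep(seq_len(n), each = 3)
  ref <- cds[cds_pos]
  alt <- unlist(lapply(cds, function(b) setdiff(bases, b)), use.names = FALSE)

  codon_index <- (cds_pos - 1L) %/% 3L + 1L
  pos_in_codon <- (cds_pos - 1L) %% 3L + 1L
  codon_start <- (codon_index - 1L) * 3L
  ref_codon <- paste0(cds[codon_start + 1L], cds[codon_start + 2L],
                      cds[codon_start + 3L])
  alt_codon <- ref_codon
  substr(alt_codon, pos_in_codon, pos_in_codon) <- alt
  ref_aa <- unname(gc_tab[ref_codon])
  alt_aa <- unname(gc_tab[alt_codon])
  impact <- ifelse(ref_aa == alt_aa, "synonymous",
                   ifelse(alt_aa == "*", "nonsense", "missense"))

  prev <- c("N", cds[-n])[cds_pos]
  nxt <- c(cds[-1], "N")[cds_pos]
  context <- paste0(prev, ref, nxt)
  gpos <- gm$cds_genomic_pos[cds_pos]
  flip <- gm$strand == "-"
  out <- data.frame(
    cds_pos = cds_pos, genomic_pos = gpos, ref = ref, alt = alt,
    ref_genome = if (flip) complement_base(ref) else ref,
    alt_genome = if (flip) complement_base(alt) else alt,
    impact = impact, trinucleotide_context = context,
    codon_index = codon_index, stringsAsFactors = FALSE)

  sp <- gm$splice_site_positions
  if (length(sp) > 0L) {
    exonic <- out$genomic_pos %in% sp
    out$impact[exonic] <- "splice"
    intronic <- setdiff(sp, gm$cds_genomic_pos)
    if (length(intronic) > 0L) {
      # intronic sequence is not part of the model: ref unknown
      sp_rows <- data.frame(
        cds_pos = NA_integer_,
        genomic_pos = rep(intronic, each = 3),
        ref = "N", alt = rep(c("A", "C", "G"), length(intronic)),
        ref_genome = "N", alt_genome = rep(c("A", "C", "G"),
                                           length(intronic)),
        impact = "splice", trinucleotide_context = "NNN",
        codon_index = NA_integer_, stringsAsFactors = FALSE)
      out <- rbind(out, sp_rows)
    }
  }
  out
}

impact_class <- function(impact) {
  ifelse(impact == "synonymous", "syn",
         ifelse(impact == "missense", "mis", "trunc"))
}

spectrum_weights <- function(impact_table, spectrum) {
  if (is.null(spectrum)) return(rep(1, nrow(impact_table)))
  assert_columns(spectrum, c("context", "alt", "rate"), "spectrum")
  if (any(spectrum$rate < 0)) stop("spectrum rates must be >= 0",
                                   call. = FALSE)
  key <- paste(impact_table$trinucleotide_context, impact_table$alt)
  w <- spectrum$rate[match(key, paste(spectrum$context, spectrum$alt))]
  # rows with unknown context (gene ends, intronic splice sites) take the
  # mean spectrum rate rather than forcing the caller to enumerate N contexts
  unknown <- grepl("N", impact_table$trinucleotide_context)
  w[unknown] <- mean(spectrum$rate)
  if (anyNA(w)) {
    stop("spectrum does not assign a rate to every (context, alt) pair in the gene",
         call. = FALSE)
  }
  w
}

#' Expected neutral class proportions of a gene
#'
#' Under neutrality, mutations fall on the enumerated substitutions in
#' proportion to the mutation-spectrum rate of their (trinucleotide context,
#' alt) class; the expected fraction of synonymous, missense and truncating
#' (nonsense + essential splice) mutations is the spectrum-weighted share of
#' each class. Scaling the spectrum by a positive constant leaves the
#' fractions unchanged.
#'
#' @param impact_table Output of [enumerate_impacts()].
#' @param spectrum `NULL` for a uniform spectrum, or a data.frame
#'   `context, alt, rate` over trinucleotide contexts.
#' @return Named numeric vector `c(e_syn, e_mis, e_trunc)` summing to 1.
#' @export
expected_class_fractions <- function(impact_table, spectrum = NULL) {
  w <- spectrum_weights(impact_table, spectrum)
  cls <- impact_class(impact_table$impact)
  tot <- sum(w)
  if (tot <= 0) {
    stop("spectrum places no mass on any substitution in the gene",
         call. = FALSE)
  }
  e <- vapply(c(syn = "syn", mis = "mis", trunc = "trunc"),
              function(k) sum(w[cls == k]) / tot, numeric(1))
  names(e) <- c("e_syn", "e_mis", "e_trunc")
  e
}

#' Classify observed mutations against an impact table
#'
#' @param observed data.frame of observed mutations, either in CDS space
#'   (`cds_pos, alt`) or genome space (`pos, alt`, matched against
#'   `genomic_pos`/`alt_genome`).
#' @param impact_table Output of [enumerate_impacts()].
#' @return `observed` with an `impact` column appended.
#' @export
classify_mutations <- function(observed, impact_table) {
  if (all(c("cds_pos", "alt") %in% names(observed))) {
    idx <- match(paste(observed$cds_pos, observed$alt),
                 paste(impact_table$cds_pos, impact_table$alt))
  } else if (all(c("pos", "alt") %in% names(observed))) {
    idx <- match(paste(observed$pos, observed$alt),
                 paste(impact_table$genomic_pos, impact_table$alt_genome))
  } else {
    stop("observed mutations need (cds_pos, alt) or (pos, alt) columns",
         call. = FALSE)
  }
  if (anyNA(idx)) {
    stop(sprintf("%d observed mutation(s) not classifiable by the impact table",
                 sum(is.na(idx))), call. = FALSE)
  }
  observed$impact <- impact_table$impact[idx]
  observed
}

# Interval for omega in the two-Poisson model n_s ~ Pois(lambda e_s),
# n_c ~ Pois(lambda e_c omega). Conditional on m = n_s + n_c, n_c is
# Binomial(m, p) with p = e_c omega / (e_s + e_c omega); inverting the exact
# Clopper-Pearson interval for p and mapping back gives an interval for
# omega with at least nominal coverage even at the single-digit counts this
# analysis sees (an asymptotic likelihood-ratio interval undercovers there:
# with an expected truncating count of ~2, observing zero must not exclude
# omega = 1).
omega_ci <- function(n_s, n_c, e_s, e_c, conf_level = 0.95) {
  omega_hat <- if (n_s == 0) Inf else (n_c / e_c) / (n_s / e_s)
  m <- n_s + n_c
  alpha <- 1 - conf_level
  p_lo <- if (n_c == 0) 0 else stats::qbeta(alpha / 2, n_c, n_s + 1)
  p_hi <- if (n_c == m) 1 else stats::qbeta(1 - alpha / 2, n_c + 1, n_s)
  to_omega <- function(p) {
    if (p >= 1) Inf else (e_s / e_c) * p / (1 - p)
  }
  c(omega = omega_hat, ci_low = to_omega(p_lo), ci_high = to_omega(p_hi))
}

#' Single-gene dN/dS estimate for truncating and missense mutations
#'
#' Models the observed synonymous, missense and truncating counts as
#' independent Poisson draws `n_class ~ Poisson(lambda * e_class *
#' omega_class)` with `omega_syn = 1`, where `e_class` are the
#' spectrum-weighted neutral class proportions of the gene and `lambda` is a
#' gene-level rate nuisance parameter. The maximum-likelihood estimate is
#' the observed/expected ratio normalized to synonymous mutations,
#' `omega_c = (n_c / e_c) / (n_syn / e_syn)`, and 95\% intervals come from
#' exact conditional inversion: given `n_syn + n_class`, the class count is
#' binomial, so Clopper--Pearson limits on its proportion map one-to-one to
#' limits on omega. The exact interval keeps at least nominal coverage at
#' the single-digit counts typical of a single gene, where the asymptotic
#' likelihood-ratio interval undercovers. With zero synonymous mutations the
#' point estimate is `Inf` but the lower bound remains finite. Positive
#' selection is declared when the truncating lower bound exceeds 1.
#'
#' @param observed data.frame of observed mutations (see
#'   [classify_mutations()]; an existing `impact` column is used as-is).
#' @param impact_table Output of [enumerate_impacts()].
#' @param spectrum Optional mutation spectrum (see
#'   [expected_class_fractions()]).
#' @param conf_level Confidence level of the intervals.
#' @return List of class `sh_selection`: per-class counts, expected
#'   proportions, `omega_truncating`, `omega_missense`, their intervals and
#'   `positive_selection`. Zero observed mutations yield an untestable
#'   result (`testable = FALSE`).
#' @export
estimate_dnds <- function(observed, impact_table, spectrum = NULL,
                          conf_level = 0.95) {
  if (!"impact" %in% names(observed)) {
    observed <- classify_mutations(observed, impact_table)
  }
  cls <- impact_class(observed$impact)
  n <- c(syn = sum(cls == "syn"), mis = sum(cls == "mis"),
         trunc = sum(cls == "trunc"))
  e <- expected_class_fractions(impact_table, spectrum)
  if (sum(n) == 0) {
    return(structure(list(testable = FALSE, n_syn = 0L, n_mis = 0L,
                          n_trunc = 0L, e_syn = e[["e_syn"]],
                          e_mis = e[["e_mis"]], e_trunc = e[["e_trunc"]],
                          omega_truncating = NA_real_,
                          omega_missense = NA_real_,
                          positive_selection = NA),
                     class = "sh_selection"))
  }
  tr <- omega_ci(n[["syn"]], n[["trunc"]], e[["e_syn"]], e[["e_trunc"]],
                 conf_level)
  mi <- omega_ci(n[["syn"]], n[["mis"]], e[["e_syn"]], e[["e_mis"]],
                 conf_level)
  structure(
    list(testable = TRUE,
         n_syn = unname(n["syn"]), n_mis = unname(n["mis"]),
         n_trunc = unname(n["trunc"]),
         e_syn = e[["e_syn"]], e_mis = e[["e_mis"]], e_trunc = e[["e_trunc"]],
         omega_truncating = tr[["omega"]],
         ci_low_truncating = tr[["ci_low"]],
         ci_high_truncating = tr[["ci_high"]],
         omega_missense = mi[["omega"]],
         ci_low_missense = mi[["ci_low"]],
         ci_high_missense = mi[["ci_high"]],
         positive_selection = tr[["ci_low"]] > 1),
    class = "sh_selection")
}

#' @export
print.sh_selection <- function(x, ...) {
  if (!x$testable) {
    cat("<selection estimate> untestable: no observed mutations\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("<selection estimate> n = %d syn / %d mis / %d trunc\n",
           "  omega_truncating = %.3g [%.3g, %.3g]\n",
           "  omega_missense   = %.3g [%.3g, %.3g]\n",
           "  positive selection (truncating): %s\n"),
    x$n_syn, x$n_mis, x$n_trunc,
    x$omega_truncating, x$ci_low_truncating, x$ci_high_truncating,
    x$omega_missense, x$ci_low_missense, x$ci_high_missense,
    x$positive_selection))
  invisible(x)
}

#' Simulate observed gene mutations with class-specific selection
#'
#' Draws mutations from the spectrum-weighted impact table with missense and
#' truncating rows up- or down-weighted by their omega; `omega = 1`
#' everywhere is the neutral model.
#'
#' @param impact_table Output of [enumerate_impacts()].
#' @param n Number of mutations to draw.
#' @param omega_trunc,omega_mis Selection coefficients.
#' @param spectrum Optional mutation spectrum.
#' @param seed Integer seed.
#' @return data.frame of drawn rows from the impact table.
#' @export
simulate_gene_mutations <- function(impact_table, n, omega_trunc = 1,
                                    omega_mis = 1, spectrum = NULL,
                                    seed = 1L) {
  w <- spectrum_weights(impact_table, spectrum)
  cls <- impact_class(impact_table$impact)
  w <- w * ifelse(cls == "trunc", omega_trunc,
                  ifelse(cls == "mis", omega_mis, 1))
  set.seed(seed)
  idx <- sample.int(nrow(impact_table), n, replace = TRUE, prob = w)
  impact_table[idx, , drop = FALSE]
}
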
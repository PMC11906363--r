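#' Load the gene-role fixture table
#'
#' Ships with the package: the 39-gene tier-1 list of recurrently mutated
#' pediatric high-grade glioma genes plus a few additional cancer genes, each
#' annotated with its mode of action (`oncogene`/`tsg`), whether copy-number
#' or point events in it qualify for tier 1, whether it mediates oncogenesis
#' via fusion events alone, and whether intragenic deletion is a recognized
#' activating mechanism.
#'
#' @param path Optional path to an alternative table.
#' @return data.frame keyed by `gene_id`.
#' @export
load_gene_roles <- function(path = NULL) {
  path <- path %||% system.file("extdata", "gene_roles.tsv",
                                package = "secondhit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load the residue-recurrence (hotspot) fixture table
#'
#' Synthetic stand-in for database-derived residue recurrence counts (the
#' live databases are version-dependent); encodes plausible counts for the
#' residues the rules need, including recurrently mutated NF1 codons.
#'
#' @param path Optional path to an alternative table.
#' @return data.frame `gene_id, residue_number, recurrence_count`.
#' @export
load_hotspots <- function(path = NULL) {
  path <- path %||% system.file("extdata", "hotspots_synthetic.tsv",
                                package = "secondhit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load the recognized oncogenic fusion fixture table
#' @param path Optional path to an alternative table.
#' @return data.frame `gene_a, gene_b` (unordered pairs).
#' @export
load_known_fusions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "known_fusions.tsv",
                                package = "secondhit")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

hotspot_recurrence <- function(gene, residue, hotspots) {
  if (is.na(residue)) return(0L)
  hit <- hotspots$gene_id == gene & hotspots$residue_number == residue
  if (any(hit)) max(hotspots$recurrence_count[hit]) else 0L
}

driver_call <- function(variant_ref, verdict, tier, rationale) {
  data.frame(variant = variant_ref, verdict = verdict,
             tier = as.character(tier), rationale = rationale,
             stringsAsFactors = FALSE)
}

gene_tier <- function(gene, gene_roles) {
  row <- gene_roles[gene_roles$gene_id == gene, ]
  if (nrow(row) == 0L) return("none")
  if (row$in_tier1_list[1]) "1" else "2"
}

#' Classify a small variant (substitution or InDel) as a driver
#'
#' Two classes of candidate drivers: missense substitutions or in-frame
#' InDels at mutation hotspots (residue recurrence > 4) of dominant-acting
#' genes, and loss-of-function mutations (nonsense, frameshift, essential
#' splice) in recessive-acting cancer genes. NF1 is handled by its own rule:
#' any inactivating mutation is a probable driver, and an NF1 missense
#' variant is a probable driver only at a residue with recurrence > 4.
#' Candidates in tier-1-list genes are tier 1, in other known cancer genes
#' tier 2.
#'
#' @param variant List or one-row data.frame with `gene`, `consequence` (one
#'   of `synonymous, missense, inframe_indel, nonsense, frameshift, splice`)
#'   and `residue` (protein position, `NA` allowed for truncating variants).
#' @param gene_roles Gene-role table ([load_gene_roles()]).
#' @param hotspots Hotspot table ([load_hotspots()]).
#' @return One-row data.frame `variant, verdict, tier, rationale`.
#' @export
classify_small_variant <- function(variant, gene_roles = load_gene_roles(),
                                   hotspots = load_hotspots()) {
  for (fld in c("gene", "consequence")) {
    if (is.null(variant[[fld]]) || is.na(variant[[fld]])) {
      stop(sprintf("variant is not annotated with '%s'", fld), call. = FALSE)
    }
  }
  gene <- variant$gene
  csq <- variant$consequence
  residue <- variant$residue %||% NA_integer_
  vref <- sprintf("%s:%s%s", gene, csq,
                  if (!is.na(residue)) paste0(":", residue) else "")
  role_row <- gene_roles[gene_roles$gene_id == gene, ]
  if (nrow(role_row) == 0L) {
    return(driver_call(vref, "not_driver", "none", "gene_not_in_census"))
  }
  role <- role_row$role[1]
  inactivating <- csq %in% c("nonsense", "frameshift", "splice")
  hotspot <- hotspot_recurrence(gene, residue, hotspots) > 4
  tier <- gene_tier(gene, gene_roles)

  if (gene == "NF1") {
    if (inactivating) {
      return(driver_call(vref, "driver", tier, "nf1_inactivating"))
    }
    if (csq %in% c("missense", "inframe_indel") && hotspot) {
      return(driver_call(vref, "driver", tier, "nf1_recurrent_residue"))
    }
    return(driver_call(vref, "not_driver", "none", "nf1_no_rule"))
  }
  if (csq %in% c("missense", "inframe_indel") &&
      role %in% c("oncogene", "both") && hotspot) {
    return(driver_call(vref, "driver", tier, "hotspot_in_dominant_gene"))
  }
  if (inactivating && role %in% c("tsg", "both")) {
    return(driver_call(vref, "driver", tier, "lof_in_recessive_gene"))
  }
  driver_call(vref, "not_driver", "none", "no_rule_matched")
}

#' Classify a copy-number segment as a driver
#'
#' Amplification and loss thresholds depend on sample ploidy: an oncogene is
#' amplified at total copy number >= 5 when ploidy < 2.7 and >= 9 when
#' ploidy >= 2.7; a tumor suppressor is lost at copy number exactly 0 when
#' ploidy < 2.7 and at copy number <= ploidy - 2.7 when ploidy >= 2.7.
#' Qualifying events are tier 1 when the gene is in the tier-1 list, the
#' segment is <= 10 Mb wide and copy-number change is a recognized oncogenic
#' mechanism for the gene (genes that act via fusion alone never qualify);
#' otherwise tier 2 when the segment is <= 1 Mb wide.
#'
#' @param segment List or one-row data.frame with `chrom, start, end,
#'   total_cn, sample_ploidy`.
#' @param genes_on_segment Character vector of genes the segment overlaps.
#' @param gene_roles Gene-role table.
#' @return data.frame with one row per gene on the segment.
#' @export
classify_copy_number <- function(segment, genes_on_segment,
                                 gene_roles = load_gene_roles()) {
  cn <- segment$total_cn
  ploidy <- segment$sample_ploidy
  if (is.null(cn) || is.na(cn) || cn < 0) {
    stop("segment total copy number must be >= 0", call. = FALSE)
  }
  width <- segment$end - segment$start + 1
  out <- lapply(genes_on_segment, function(gene) {
    vref <- sprintf("%s:%s:%d-%d:CN=%g", gene, segment$chrom, segment$start,
                    segment$end, cn)
    role_row <- gene_roles[gene_roles$gene_id == gene, ]
    if (nrow(role_row) == 0L) {
      return(driver_call(vref, "not_driver", "none", "gene_not_in_census"))
    }
    role <- role_row$role[1]
    amplified <- role %in% c("oncogene", "both") &&
      ((ploidy < 2.7 && cn >= 5) || (ploidy >= 2.7 && cn >= 9))
    lost <- role %in% c("tsg", "both") &&
      ((ploidy < 2.7 && cn == 0) || (ploidy >= 2.7 && cn <= ploidy - 2.7))
    if (!amplified && !lost) {
      return(driver_call(vref, "not_driver", "none", "cn_threshold_not_met"))
    }
    rule <- if (amplified) "oncogene_amplification" else "tsg_loss"
    if (role_row$in_tier1_list[1] && width <= 10e6 &&
        !role_row$fusion_only[1]) {
      driver_call(vref, "driver", "1", rule)
    } else if (width <= 1e6) {
      driver_call(vref, "driver", "2", rule)
    } else {
      driver_call(vref, "not_driver", "none", "segment_too_wide")
    }
  })
  do.call(rbind, out)
}

#' Classify a structural variant as a driver
#'
#' A structural variant is a driver, independent of copy-number state, when
#' it forms a fusion gene recognized to be oncogenic, truncates the
#' footprint of a tumor suppressor gene, or activates an oncogene through
#' intragenic deletion (a mechanism flagged per gene). Tier 1 when the
#' implicated gene is in the tier-1 list, tier 2 otherwise.
#'
#' @param sv List with `type` (`deletion, inversion, translocation,
#'   tandem_dup`) and `breakpoint_genes` (character vector of length 2; `NA`
#'   where a breakpoint falls outside any gene).
#' @param gene_roles Gene-role table.
#' @param known_fusions Recognized-fusion table ([load_known_fusions()]).
#' @return One-row data.frame `variant, verdict, tier, rationale`.
#' @export
classify_structural <- function(sv, gene_roles = load_gene_roles(),
                                known_fusions = load_known_fusions()) {
  genes <- sv$breakpoint_genes
  if (length(genes) != 2L) {
    stop("sv$breakpoint_genes must have length 2 (NA for intergenic ends)",
         call. = FALSE)
  }
  known_genes <- unique(c(gene_roles$gene_id, known_fusions$gene_a,
                          known_fusions$gene_b))
  unknown <- genes[!is.na(genes) & !(genes %in% known_genes)]
  if (length(unknown) > 0L) {
    stop(sprintf("breakpoint gene(s) outside supplied annotation: %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  vref <- sprintf("%s:%s-%s", sv$type,
                  ifelse(is.na(genes[1]), ".", genes[1]),
                  ifelse(is.na(genes[2]), ".", genes[2]))
  if (all(is.na(genes))) {
    return(driver_call(vref, "not_driver", "none", "no_gene_contact"))
  }
  tier_of <- function(g) gene_tier(g, gene_roles)
  # recognized oncogenic fusion (unordered pair)
  if (!anyNA(genes) && genes[1] != genes[2]) {
    pair_key <- paste(sort(genes), collapse = "|")
    fus_keys <- apply(known_fusions, 1,
                      function(r) paste(sort(c(r[["gene_a"]], r[["gene_b"]])),
                                        collapse = "|"))
    if (pair_key %in% fus_keys) {
      tiers <- vapply(genes, tier_of, character(1))
      tier <- if ("1" %in% tiers) "1" else "2"
      return(driver_call(vref, "driver", tier, "oncogenic_fusion"))
    }
  }
  # activating intragenic deletion of an oncogene
  if (identical(sv$type, "deletion") && !anyNA(genes) &&
      genes[1] == genes[2]) {
    row <- gene_roles[gene_roles$gene_id == genes[1], ]
    if (nrow(row) == 1L && row$role %in% c("oncogene", "both") &&
        isTRUE(row$activating_intragenic_del)) {
      return(driver_call(vref, "driver", tier_of(genes[1]),
                         "activating_intragenic_deletion"))
    }
  }
  # truncation of a tumor suppressor footprint
  for (g in unique(stats::na.omit(genes))) {
    row <- gene_roles[gene_roles$gene_id == g, ]
    if (nrow(row) == 1L && row$role %in% c("tsg", "both")) {
      return(driver_call(vref, "driver", tier_of(g), "tsg_truncation"))
    }
  }
  driver_call(vref, "not_driver", "none", "no_rule_matched")
}
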
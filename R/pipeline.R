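#' Default pipeline analysis parameters
#'
#' Thresholds mirror the analysis gates: presence and LOH significance at
#' BH q < 0.01, per-SNP coverage floor 10x, median-coverage gate 30x,
#' purity gate 1\%, 1,000 permutation draws. The dN/dS demonstration uses an
#' NF1-sized synthetic gene (2,840 codons, 8,520 bp) with a 10-fold
#' truncating excess over 40 mutations.
#'
#' @return Named list of parameters.
#' @export
default_pipeline_params <- function() {
  list(q_presence = 0.01, q_loh = 0.01, min_site_depth = 10,
       min_median_coverage = 30, max_purity = 0.01, n_draws = 1000,
       min_alt = 2, duplex_single_strand_error = 1e-3,
       dnds = list(n_codons = 2840, n_mutations = 40, omega_trunc = 10,
                   omega_mis = 1),
       expansion_threshold = 100)
}

second_hit_nodes <- function(individual) {
  if (nrow(individual$clones) == 0L) return(integer(0))
  individual$clones$node_id
}

sample_has_second_hit <- function(individual, spec) {
  hit_nodes <- second_hit_nodes(individual)
  if (length(hit_nodes) == 0L) return(FALSE)
  any(vapply(as.integer(names(spec$clone_fractions)), function(nd) {
    any(hit_nodes %in% root_path(individual$tree, nd))
  }, logical(1)))
}

#' Run the full second-hit analysis pipeline on a synthetic cohort
#'
#' Executes the stages in dependency order -- simulate, contamination,
#' phasing/LOH, genotyping, shared ancestry, selection (dN/dS), driver
#' annotation, duplex calling, burden model -- writing each stage's tables
#' under `outdir` and a manifest (`manifest.json`) listing every artifact
#' with its MD5 checksum, the seeds used and every threshold applied.
#'
#' @param config Cohort configuration ([default_cohort_config()]) or a path
#'   to a JSON/YAML config.
#' @param outdir Output directory (created if needed).
#' @param seed Master seed; stage seeds are derived from it.
#' @param params Analysis parameters ([default_pipeline_params()]).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = default_cohort_config(), outdir,
                         seed = 1L, params = default_pipeline_params()) {
  if (is.character(config)) config <- read_cohort_config(config)
  validate_cohort_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("secondhit")),
                   seed = seed, params = params, stages = list(),
                   files = list())
  note <- function(stage, status = "ok") {
    manifest$stages[[stage]] <<- status
  }
  register_file <- function(name) {
    manifest$files[[name]] <<- unname(tools::md5sum(file.path(outdir, name)))
  }
  emit_file <- function(x, name) {
    path <- file.path(outdir, name)
    if (is.data.frame(x)) write_tsv(x, path)
    else jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE, force = TRUE, na = "null")
    register_file(name)
    path
  }

  run <- function(expr, stage) {
    tryCatch(expr, error = function(e) {
      note(stage, paste("failed:", conditionMessage(e)))
      emit_file(manifest, "manifest.json")
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## 1. simulate -----------------------------------------------------------
  cohort <- run({
    ch <- simulate_cohort(config, seed)
    pb <- ch$proband
    sites <- rbind(snp_sites(pb),
                   mutation_sites(pb, include_germline = TRUE)[,
                     c("chrom", "pos", "ref", "alt")])
    rc <- emit_all_read_counts(pb, sites, derive_seed(seed, "reads"))
    emit_file(rc, "proband_read_counts.tsv")
    cand <- pb$clones[pb$clones$type == "point", , drop = FALSE]
    cand_sites <- pb$tree$catalog[
      pb$tree$catalog$mutation_id %in% cand$point_mutation_id, , drop = FALSE]
    ctl_rc <- do.call(rbind, lapply(ch[-1], function(ctl) {
      emit_all_read_counts(ctl, mutation_sites(pb)[, c("chrom", "pos", "ref",
                                                       "alt")],
                           derive_seed(seed, paste0("ctl_reads_", ctl$id)))
    }))
    emit_file(ctl_rc, "control_read_counts.tsv")
    vcf <- rbind(pb$germline,
                 pb$tree$catalog[, c("chrom", "pos", "ref", "alt")])
    emit_file(data.frame(truth = "see fields",
                         n_samples = length(pb$samples)),
              "truth_summary.tsv")
    write_simple_vcf(vcf, file.path(outdir, "proband_variants.vcf"))
    register_file("proband_variants.vcf")
    note("simulate")
    list(cohort = ch, read_counts = rc, control_counts = ctl_rc,
         candidate_sites = cand_sites)
  }, "simulate")
  pb <- cohort$cohort$proband
  rc <- cohort$read_counts

  ## 2. tumor contamination -------------------------------------------------
  purity <- run({
    truncal <- pb$tree$catalog[pb$tree$catalog$mutation_id %in%
                                 truncal_mutations(pb), , drop = FALSE]
    truncal <- truncal[truncal$chrom != pb$gene$chrom, , drop = FALSE]
    pur <- estimate_purity_all(truncal, rc)
    emit_file(pur, "purity.tsv")
    note("contamination")
    pur
  }, "contamination")

  ## 3. phasing + LOH -------------------------------------------------------
  loh <- run({
    tumor_id <- pb$samples[[1]]$sample_id
    phased <- phase_by_tumor(pb$snps, rc[rc$sample_id == tumor_id, ])
    emit_file(phased, "phased_snps.tsv")
    normal_rc <- rc[rc$sample_id != tumor_id, ]
    calls <- test_loh(normal_rc, phased, purity,
                      min_site_depth = params$min_site_depth,
                      q_threshold = params$q_loh,
                      min_median_coverage = params$min_median_coverage,
                      max_purity = params$max_purity)
    emit_file(calls, "loh_calls.tsv")
    note("phasing_loh")
    calls
  }, "phasing_loh")

  ## 4. point-mutation genotyping -------------------------------------------
  genotypes <- run({
    g <- genotype_presence(cohort$candidate_sites, rc,
                           cohort$control_counts,
                           q_threshold = params$q_presence)
    emit_file(g, "genotype_calls.tsv")
    note("genotyping")
    g
  }, "genotyping")

  ## 5. shared ancestry ------------------------------------------------------
  ancestry <- run({
    tumor_id <- pb$samples[[1]]$sample_id
    norm_specs <- Filter(function(s) s$sample_id != tumor_id, pb$samples)
    somatic <- mutation_sites(pb)
    somatic <- somatic[!(somatic$mutation_id %in% truncal_mutations(pb)), ]
    # error panel from the control individuals (no shared somatic ancestry)
    presence <- genotype_presence(
      somatic, rc[rc$sample_id != tumor_id, ], cohort$control_counts,
      q_threshold = params$q_presence, min_alt = params$min_alt)
    hit <- vapply(norm_specs, function(s) sample_has_second_hit(pb, s),
                  logical(1))
    clean <- vapply(norm_specs, function(s) {
      p <- purity$purity[purity$sample_id == s$sample_id]
      length(p) == 1 && p < params$max_purity
    }, logical(1))
    strat <- vapply(norm_specs, function(s) s$stratum %||% "CNS",
                    character(1))
    ids <- vapply(norm_specs, `[[`, character(1), "sample_id")
    # test pairs: samples whose clones descend from the same point-hit node
    point_nodes <- pb$clones$node_id[pb$clones$type == "point"]
    sharing_test <- do.call(rbind, lapply(point_nodes, function(nd) {
      carriers <- ids[vapply(norm_specs, function(s) {
        any(vapply(as.integer(names(s$clone_fractions)), function(x)
          nd %in% root_path(pb$tree, x), logical(1)))
      }, logical(1))]
      if (length(carriers) < 2L) return(NULL)
      pairwise_sharing(presence, carriers, group = "test")
    }))
    if (is.null(sharing_test)) {
      stop("no point second hit is carried by two or more samples",
           call. = FALSE)
    }
    ctl_ids <- ids[!hit & clean & strat == "CNS"]
    sharing_ctl <- pairwise_sharing(presence, ctl_ids, group = "control")
    emit_file(rbind(sharing_test, sharing_ctl), "pair_sharing.tsv")
    perm <- permutation_test(sharing_test$shared_count,
                             sharing_ctl$shared_count,
                             n_draws = params$n_draws,
                             seed = derive_seed(seed, "permutation"))
    emit_file(unclass(perm), "permutation.json")
    note("ancestry")
    list(presence = presence, perm = perm, norm_ids = ids, hit = hit,
         specs = norm_specs)
  }, "ancestry")

  ## 6. selection (dN/dS) ----------------------------------------------------
  selection <- run({
    gm <- random_gene_model(params$dnds$n_codons,
                            seed = derive_seed(seed, "gene_model"),
                            gene_id = pb$gene$gene_id,
                            chrom = pb$gene$chrom, start = pb$gene$start)
    impacts <- enumerate_impacts(gm)
    obs <- simulate_gene_mutations(impacts, params$dnds$n_mutations,
                                   omega_trunc = params$dnds$omega_trunc,
                                   omega_mis = params$dnds$omega_mis,
                                   seed = derive_seed(seed, "dnds_obs"))
    est <- estimate_dnds(obs, impacts)
    counts <- data.frame(class = c("synonymous", "missense", "truncating"),
                         observed = c(est$n_syn, est$n_mis, est$n_trunc),
                         expected_fraction = c(est$e_syn, est$e_mis,
                                               est$e_trunc))
    emit_file(counts, "dnds_class_counts.tsv")
    emit_file(unclass(est)[setdiff(names(unclass(est)), "fit")],
              "dnds_estimate.json")
    note("selection")
    est
  }, "selection")

  ## 7. driver annotation ----------------------------------------------------
  drivers <- run({
    roles <- load_gene_roles()
    hotspots <- load_hotspots()
    fusions <- load_known_fusions()
    planted <- pb$clones[pb$clones$type == "point", , drop = FALSE]
    calls <- do.call(rbind, c(
      lapply(seq_len(nrow(planted)), function(i) {
        classify_small_variant(list(gene = pb$gene$gene_id,
                                    consequence = "nonsense", residue = 304L),
                               roles, hotspots)
      }),
      list(
        classify_copy_number(list(chrom = "4", start = 54000000,
                                  end = 56000000, total_cn = 6,
                                  sample_ploidy = 2.0),
                             "PDGFRA", roles),
        classify_structural(list(type = "deletion",
                                 breakpoint_genes = c("NF1", "NF1")),
                            roles, fusions))))
    emit_file(calls, "driver_calls.tsv")
    note("drivers")
    calls
  }, "drivers")

  ## 8. duplex calling -------------------------------------------------------
  duplex <- run({
    cand <- cohort$candidate_sites[, c("chrom", "pos", "ref", "alt")]
    germ <- pb$germline
    dsites <- rbind(cand, germ)
    bundles <- do.call(rbind, lapply(pb$samples[-1], function(s) {
      emit_duplex_reads(pb, s, dsites,
                        single_strand_error = params$duplex_single_strand_error,
                        seed = derive_seed(seed, "duplex"))
    }))
    calls <- call_duplex(bundles, matched_normal_calls = germ)
    emit_file(calls, "duplex_calls.tsv")
    note("duplex")
    calls
  }, "duplex")

  ## 9. burden model ---------------------------------------------------------
  burden <- run({
    pres <- ancestry$presence
    ids <- ancestry$norm_ids
    counts <- vapply(ids, function(s) {
      sum(pres$present[pres$sample_id == s])
    }, numeric(1))
    recs <- data.frame(
      sample_id = ids, substitution_count = counts,
      nf1_null = ancestry$hit,
      modality = vapply(ancestry$specs, `[[`, character(1), "modality"),
      coverage = vapply(ancestry$specs, `[[`, double(1), "target_depth"),
      tissue_piece_id = vapply(ancestry$specs, function(s)
        s$tissue_piece_id %||% s$sample_id, character(1)),
      stringsAsFactors = FALSE)
    fit <- fit_burden_model(recs,
                            expansion_threshold = params$expansion_threshold)
    emit_file(recs, "burden_records.tsv")
    emit_file(list(effect = fit$effect, se = fit$se, p_value = fit$p_value,
                   expansion_verdict = fit$expansion_verdict,
                   model = fit$model), "burden_model.json")
    note("burden")
    fit
  }, "burden")

  emit_file(manifest, "manifest.json")
  invisible(manifest)
}
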
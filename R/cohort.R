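#' Default synthetic-cohort configuration
#'
#' Encodes the study conditions the analysis assumes: one proband carrying a
#' heterozygous germline truncating hit in a large recessive
#' cancer-predisposition gene on chromosome 17 (an NF1-like footprint), whose
#' tumor shows complete chromosome-17 copy-neutral LOH retaining the mutant
#' haplotype, together with two unaffected control individuals. Normal-tissue
#' samples of the proband are mixtures of lineage-tree clones; some clones
#' carry independent second hits (a truncating point mutation, CN-LOH losing
#' either parental haplotype, or a one-copy deletion) at cell fractions
#' spanning the 2\%--56\% range observed for such clones. Read counts are
#' Poisson/binomial with a per-base error rate of 1e-3, and low-level tumor
#' contamination (0.5\%) is planted in a subset of samples, with one heavily
#' contaminated sample (5\%) that the purity gate must exclude.
#'
#' The lineage topology is explicit so that every downstream truth (clone
#' fractions, shared-mutation counts, truncal sets) is exactly known.
#'
#' @return A nested list; see the field names for structure. Serializable to
#'   JSON/YAML via [write_cohort_config()].
#' @export
default_cohort_config <- function() {
  # explicit topology: 1 root; 2-3 tumor lineage; 4 CNS ancestor; 10 MES
  parents <- c(NA, 1, 2, 1, 4, 5, 5, 4, 4, 1, 10, 10, 4, 4, 4, 4, 10, 10)
  sample_spec <- function(id, node, fraction, contamination = 0,
                          modality = "lcm", depth = 30, stratum = "CNS",
                          tissue_piece = id) {
    list(sample_id = id, modality = modality,
         clone_fractions = stats::setNames(fraction, as.character(node)),
         tumor_contamination = contamination, target_depth = depth,
         error_rate = 1e-3, stratum = stratum, tissue_piece_id = tissue_piece)
  }
  list(
    genome = list(chroms = as.character(1:22), chrom_length = 8e7),
    gene = list(gene_id = "NF1", chrom = "17",
                start = 31094927, end = 31377677),
    snp_panel = list(n_snps = 1000, chrom = "17",
                     start = 25000000, end = 40000000),
    branch_mutation_rate = 150,
    n_truncal = 300,
    proband = list(
      id = "PB",
      parents = parents,
      germline = list(chrom = "17", pos = 31204560, ref = "G", alt = "A"),
      tumor = list(node = 3, mechanism = "cnloh", lost = "wt"),
      clones = list(
        list(id = "point_shared", node = 5, type = "point"),
        list(id = "loh13",  node = 8,  type = "loh", lost = "wt",
             mechanism = "cnloh"),
        list(id = "loh02",  node = 9,  type = "loh", lost = "wt",
             mechanism = "cnloh"),
        list(id = "mutloss", node = 11, type = "loh", lost = "mutant",
             mechanism = "cnloh"),
        list(id = "del15",  node = 12, type = "loh", lost = "wt",
             mechanism = "deletion")
      ),
      samples = list(
        sample_spec("PB_T", 3, 0.95, modality = "bulk", depth = 40,
                    tissue_piece = "tumor"),
        sample_spec("PB_shared_A", 6, 0.90),
        sample_spec("PB_shared_B", 7, 0.90),
        sample_spec("PB_point", 5, 0.56),
        sample_spec("PB_loh13", 8, 0.13),
        sample_spec("PB_loh02", 9, 0.02),
        sample_spec("PB_mutloss", 11, 0.10, stratum = "MES"),
        sample_spec("PB_del", 12, 0.15, stratum = "MES"),
        sample_spec("PB_norm_1", 13, 0.95, contamination = 0.005,
                    tissue_piece = "piece_cns_a"),
        sample_spec("PB_norm_2", 14, 0.95, tissue_piece = "piece_cns_a"),
        sample_spec("PB_norm_3", 15, 0.95, tissue_piece = "piece_cns_b"),
        sample_spec("PB_norm_4", 16, 0.95, tissue_piece = "piece_cns_b"),
        sample_spec("PB_cont", 14, 0.90, contamination = 0.05,
                    tissue_piece = "piece_cns_a"),
        sample_spec("PB_mes_1", 17, 0.95, contamination = 0.005,
                    stratum = "MES", tissue_piece = "piece_mes_a"),
        sample_spec("PB_mes_2", 18, 0.95, stratum = "MES",
                    tissue_piece = "piece_mes_a")
      )
    ),
    controls = list(
      list(id = "C1",
           parents = c(NA, 1, 1, 2, 2, 3, 3),
           samples = list(
             sample_spec("C1_1", 4, 0.95), sample_spec("C1_2", 5, 0.95),
             sample_spec("C1_3", 6, 0.95, stratum = "MES"),
             sample_spec("C1_4", 7, 0.95, stratum = "MES"))),
      list(id = "C2",
           parents = c(NA, 1, 1, 2, 2, 3, 3),
           samples = list(
             sample_spec("C2_1", 4, 0.95), sample_spec("C2_2", 5, 0.95),
             sample_spec("C2_3", 6, 0.95, stratum = "MES"),
             sample_spec("C2_4", 7, 0.95, stratum = "MES")))
    )
  )
}

#' Validate a cohort configuration
#'
#' Checks the structural invariants the simulator relies on: a well-formed
#' tree topology per individual, clone nodes inside the tree, point second
#' hits restricted to the predisposition-gene footprint (they are placed
#' there by construction), and per-sample clone fractions plus tumor
#' contamination summing to at most 1.
#'
#' @param config A cohort configuration list.
#' @return `config`, invisibly, if valid; otherwise an error.
#' @export
validate_cohort_config <- function(config) {
  for (fld in c("genome", "gene", "snp_panel", "proband", "controls")) {
    if (is.null(config[[fld]])) {
      stop(sprintf("config is missing field '%s'", fld), call. = FALSE)
    }
  }
  check_individual <- function(ind, has_clones) {
    parents <- unlist(ind$parents)
    if (sum(is.na(parents)) != 1L || !is.na(parents[1])) {
      stop("topology must have exactly one root at node 1", call. = FALSE)
    }
    if (any(stats::na.omit(parents >= seq_along(parents)))) {
      stop("parents must precede children (acyclic topology)", call. = FALSE)
    }
    for (s in ind$samples) {
      total <- sum(unlist(s$clone_fractions)) +
        (s$tumor_contamination %||% 0)
      if (total > 1 + 1e-12) {
        stop(sprintf("sample %s: clone fractions + contamination exceed 1",
                     s$sample_id), call. = FALSE)
      }
      if (any(unlist(s$clone_fractions) < 0) || s$target_depth < 0) {
        stop(sprintf("sample %s: negative fraction or depth", s$sample_id),
             call. = FALSE)
      }
      nodes <- as.integer(names(s$clone_fractions))
      if (any(nodes < 1 | nodes > length(parents))) {
        stop(sprintf("sample %s references nodes outside the tree",
                     s$sample_id), call. = FALSE)
      }
    }
    if (has_clones) {
      for (cl in ind$clones) {
        if (cl$type == "loh" && !(cl$lost %in% c("wt", "mutant"))) {
          stop("loh clone must lose exactly one parental haplotype ('wt' or 'mutant')",
               call. = FALSE)
        }
      }
    }
  }
  check_individual(config$proband, has_clones = TRUE)
  for (ctl in config$controls) check_individual(ctl, has_clones = FALSE)
  invisible(config)
}

#' Simulate a synthetic cohort
#'
#' Builds the proband and control individuals described by `config`:
#' lineage trees with Poisson branch mutations over the configured topology,
#' a chromosome-17 heterozygous SNP panel with per-individual haplotype
#' truth, the proband's germline hit (present in every proband cell), the
#' tumor clone with whole-chromosome-17 LOH retaining the mutant haplotype,
#' and the planted second-hit clones. Controls carry no second hits.
#'
#' @param config Cohort configuration (see [default_cohort_config()]).
#' @param seed Master seed. Child seeds are derived per individual/stage, so
#'   the whole cohort is reproducible byte-for-byte.
#' @return List with elements `proband`, `control_1`, `control_2`, each an
#'   object of class `sh_individual`.
#' @export
simulate_cohort <- function(config = default_cohort_config(), seed = 1L) {
  # normalize numeric types so a JSON round-tripped config reproduces the
  # in-memory default byte-for-byte
  config$genome$chrom_length <- as.numeric(config$genome$chrom_length)
  for (fld in c("start", "end")) {
    config$gene[[fld]] <- as.numeric(config$gene[[fld]])
    config$snp_panel[[fld]] <- as.numeric(config$snp_panel[[fld]])
  }
  config$snp_panel$n_snps <- as.integer(config$snp_panel$n_snps)
  config$branch_mutation_rate <- as.numeric(config$branch_mutation_rate)
  config$n_truncal <- as.integer(config$n_truncal)
  validate_cohort_config(config)
  proband <- build_individual(config, config$proband, is_proband = TRUE,
                              seed = derive_seed(seed, "proband"))
  controls <- lapply(seq_along(config$controls), function(i) {
    build_individual(config, config$controls[[i]], is_proband = FALSE,
                     seed = derive_seed(seed, paste0("control_", i)))
  })
  out <- c(list(proband = proband), controls)
  names(out) <- c("proband", paste0("control_", seq_along(controls)))
  out
}

build_individual <- function(config, ind_cfg, is_proband, seed) {
  parents <- unlist(ind_cfg$parents)
  n_nodes <- length(parents)
  # somatic mutations avoid chromosome 17 so LOH copy states never interact
  # with lineage markers; second hits in the gene are added explicitly below
  somatic_chroms <- setdiff(config$genome$chroms, config$gene$chrom)
  tree <- simulate_lineage(n_nodes, config$branch_mutation_rate,
                           seed = derive_seed(seed, "tree"),
                           chroms = somatic_chroms,
                           chrom_length = config$genome$chrom_length,
                           parents = parents)

  set.seed(derive_seed(seed, "snps"))
  sp <- config$snp_panel
  pos <- sort(sample.int(sp$end - sp$start + 1, sp$n_snps)) +
    as.integer(sp$start) - 1L
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, sp$n_snps, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
                USE.NAMES = FALSE)
  snps <- data.frame(chrom = sp$chrom, pos = pos, ref = ref, alt = alt,
                     alt_on_hap_a = sample(c(TRUE, FALSE), sp$n_snps,
                                           replace = TRUE),
                     stringsAsFactors = FALSE)

  germline <- NULL
  tumor <- NULL
  clones <- data.frame(clone_id = character(0), node_id = integer(0),
                       type = character(0), point_mutation_id = integer(0),
                       lost = character(0), mechanism = character(0),
                       stringsAsFactors = FALSE)
  if (is_proband) {
    g <- ind_cfg$germline
    germline <- data.frame(chrom = g$chrom, pos = as.integer(g$pos),
                           ref = g$ref, alt = g$alt, stringsAsFactors = FALSE)
    tumor <- ind_cfg$tumor
    tumor$node <- as.integer(tumor$node)
    # truncal boost: extra substitutions on the tumor's own branch
    set.seed(derive_seed(seed, "truncal"))
    n_tr <- config$n_truncal
    if (n_tr > 0) {
      ids <- max(0L, tree$catalog$mutation_id) + seq_len(n_tr)
      tr_ref <- sample(bases, n_tr, replace = TRUE)
      extra <- data.frame(
        mutation_id = ids,
        chrom = sample(somatic_chroms, n_tr, replace = TRUE),
        pos = sample.int(config$genome$chrom_length, n_tr, replace = TRUE),
        ref = tr_ref,
        alt = vapply(tr_ref, function(r) sample(setdiff(bases, r), 1L),
                     character(1), USE.NAMES = FALSE),
        stringsAsFactors = FALSE)
      tree$catalog <- rbind(tree$catalog, extra)
      tree$branch_mutations[[tumor$node]] <-
        c(tree$branch_mutations[[tumor$node]], ids)
    }
    # planted second-hit clones
    set.seed(derive_seed(seed, "clones"))
    for (cl in ind_cfg$clones) {
      pm_id <- NA_integer_
      if (cl$type == "point") {
        pm_id <- max(tree$catalog$mutation_id) + 1L
        p <- sample.int(config$gene$end - config$gene$start + 1, 1L) +
          as.integer(config$gene$start) - 1L
        r <- sample(bases, 1L)
        tree$catalog <- rbind(tree$catalog, data.frame(
          mutation_id = pm_id, chrom = config$gene$chrom, pos = p, ref = r,
          alt = sample(setdiff(bases, r), 1L), stringsAsFactors = FALSE))
        tree$branch_mutations[[cl$node]] <-
          c(tree$branch_mutations[[cl$node]], pm_id)
      }
      clones <- rbind(clones, data.frame(
        clone_id = cl$id, node_id = as.integer(cl$node), type = cl$type,
        point_mutation_id = pm_id, lost = cl$lost %||% NA_character_,
        mechanism = cl$mechanism %||% NA_character_,
        stringsAsFactors = FALSE))
    }
  }

  structure(
    list(id = ind_cfg$id, tree = tree, snps = snps, germline = germline,
         tumor = tumor, clones = clones, samples = ind_cfg$samples,
         gene = config$gene, genome = config$genome),
    class = "sh_individual")
}

#' @export
print.sh_individual <- function(x, ...) {
  cat(sprintf("<sh_individual> %s: %d nodes, %d samples, %d second-hit clones\n",
              x$id, nrow(x$tree$nodes), length(x$samples), nrow(x$clones)))
  invisible(x)
}

#' Truncal tumor mutations of an individual
#'
#' Mutation ids on the tumor node's root path: the set present in every tumor
#' cell, used to quantify tumor contamination of other samples.
#'
#' @param individual An `sh_individual` with a tumor clone.
#' @return Integer vector of mutation ids.
#' @export
truncal_mutations <- function(individual) {
  if (is.null(individual$tumor)) {
    stop("individual has no tumor clone", call. = FALSE)
  }
  node_genotype(individual$tree, individual$tumor$node)
}

get_sample_spec <- function(individual, sample) {
  if (is.list(sample)) return(sample)
  ids <- vapply(individual$samples, `[[`, character(1), "sample_id")
  hit <- which(ids == sample)
  if (length(hit) != 1L) {
    stop(sprintf("unknown sample '%s'", sample), call. = FALSE)
  }
  individual$samples[[hit]]
}

# The cell populations making up a sample: planned clone fractions, tumor
# contamination, and a wild-type background filling the remainder. Each
# population carries its LOH state (inherited from any LOH clone, or the
# tumor, on its node's root path).
sample_populations <- function(individual, spec) {
  nodes <- as.integer(names(spec$clone_fractions))
  fracs <- as.numeric(unlist(spec$clone_fractions))
  cont <- spec$tumor_contamination %||% 0
  if (cont > 0) {
    if (is.null(individual$tumor)) {
      stop("tumor contamination requested but individual has no tumor",
           call. = FALSE)
    }
    nodes <- c(nodes, individual$tumor$node)
    fracs <- c(fracs, cont)
  }
  bg <- 1 - sum(fracs)
  if (bg < -1e-12) stop("population fractions exceed 1", call. = FALSE)
  if (bg > 1e-12) {
    nodes <- c(nodes, 1L) # root: germline-only background
    fracs <- c(fracs, bg)
  }

  loh_nodes <- integer(0); loh_lost <- character(0); loh_mech <- character(0)
  if (nrow(individual$clones) > 0) {
    loh_cl <- individual$clones[individual$clones$type == "loh", ]
    loh_nodes <- loh_cl$node_id
    loh_lost <- loh_cl$lost
    loh_mech <- loh_cl$mechanism
  }
  if (!is.null(individual$tumor)) {
    loh_nodes <- c(loh_nodes, individual$tumor$node)
    loh_lost <- c(loh_lost, individual$tumor$lost)
    loh_mech <- c(loh_mech, individual$tumor$mechanism)
  }

  pop_loh <- lapply(nodes, function(n) {
    path <- root_path(individual$tree, n)
    hit <- which(loh_nodes %in% path)
    if (length(hit) == 0L) return(NULL)
    list(lost = loh_lost[hit[1]], mechanism = loh_mech[hit[1]])
  })
  list(nodes = nodes, fractions = fracs, loh = pop_loh)
}

# classify query sites against the individual's variant registries
annotate_sites <- function(individual, sites) {
  assert_columns(sites, c("chrom", "pos", "ref", "alt"), "sites")
  ok <- sites$chrom %in% individual$genome$chroms &
    sites$pos >= 1 & sites$pos <= individual$genome$chrom_length
  if (!all(ok)) {
    stop(sprintf("%d site(s) fall outside the simulated genome", sum(!ok)),
         call. = FALSE)
  }
  key <- site_key(sites$chrom, sites$pos, sites$ref, sites$alt)
  snp_idx <- match(key, site_key(individual$snps$chrom, individual$snps$pos,
                                 individual$snps$ref, individual$snps$alt))
  cat_idx <- match(key, site_key(individual$tree$catalog$chrom,
                                 individual$tree$catalog$pos,
                                 individual$tree$catalog$ref,
                                 individual$tree$catalog$alt))
  is_germ <- if (!is.null(individual$germline)) {
    key == site_key(individual$germline$chrom, individual$germline$pos,
                    individual$germline$ref, individual$germline$alt)
  } else rep(FALSE, length(key))
  type <- rep("ref", length(key))
  type[!is.na(cat_idx)] <- "somatic"
  type[!is.na(snp_idx)] <- "snp"
  type[is_germ] <- "germline"
  list(type = type, snp_idx = snp_idx, cat_idx = cat_idx,
       on_chr17 = sites$chrom == individual$gene$chrom)
}

#' Expected variant allele fraction of sites in a sample
#'
#' Computes the exact population-weighted allele dosage for each queried
#' site, before sequencing noise: heterozygous variants contribute one of
#' two copies per carrier cell, LOH populations contribute 0 or 2 of 2
#' (CN-LOH) or 0 or 1 of 1 (deletion) copies of chromosome-17 alleles
#' depending on which parental haplotype they retained.
#'
#' @param individual An `sh_individual`.
#' @param sample A sample id or a sample-spec list of that individual.
#' @param sites data.frame with `chrom, pos, ref, alt` (1-based, closed).
#' @return Numeric vector of expected allele fractions, one per site.
#' @export
true_vaf <- function(individual, sample, sites) {
  spec <- get_sample_spec(individual, sample)
  pops <- sample_populations(individual, spec)
  ann <- annotate_sites(individual, sites)
  n <- nrow(sites)

  genos <- lapply(pops$nodes, function(nd) node_genotype(individual$tree, nd))
  alt_w <- numeric(n)
  tot_w <- numeric(n)
  for (i in seq_along(pops$nodes)) {
    f <- pops$fractions[i]
    loh <- pops$loh[[i]]
    alt_c <- numeric(n)
    tot_c <- rep(2, n)

    is_snp <- ann$type == "snp"
    is_germ <- ann$type == "germline"
    is_som <- ann$type == "somatic"

    if (is.null(loh)) {
      if (any(is_snp)) alt_c[is_snp] <- 1            # germline het SNP
      if (any(is_germ)) alt_c[is_germ] <- 1          # germline hit, het
    } else {
      retained_a <- loh$lost == "wt"                 # hap A = mutant hap
      cn <- if (loh$mechanism == "deletion") 1 else 2
      affected <- ann$on_chr17
      tot_c[affected] <- cn
      if (any(is_snp)) {
        on_a <- individual$snps$alt_on_hap_a[ann$snp_idx[is_snp]]
        alt_c[is_snp] <- ifelse(xor(on_a, !retained_a), cn, 0)
        # SNPs off chr17 would be diploid het, but panel is chr17-only
        off <- is_snp & !affected
        if (any(off)) alt_c[off] <- 1
      }
      if (any(is_germ)) alt_c[is_germ] <- if (retained_a) cn else 0
    }
    if (any(is_som)) {
      mid <- individual$tree$catalog$mutation_id[ann$cat_idx[is_som]]
      alt_c[is_som] <- as.numeric(mid %in% genos[[i]])
    }
    alt_w <- alt_w + f * alt_c
    tot_w <- tot_w + f * tot_c
  }
  ifelse(tot_w > 0, alt_w / tot_w, 0)
}

#' Emit per-site read counts for one sample
#'
#' Sequencing model: depth ~ Poisson(`target_depth`); alt reads ~
#' Binomial(depth, v) with `v = vaf * (1 - e) + (1 - vaf) * e / 3`, where a
#' base-calling error lands on the specific alt allele with probability
#' `e / 3` (uniform over the three non-reference bases).
#'
#' @inheritParams true_vaf
#' @param seed Integer seed.
#' @return data.frame with `sample_id, chrom, pos, ref, alt, depth, alt_depth`.
#' @export
emit_read_counts <- function(individual, sample, sites, seed) {
  spec <- get_sample_spec(individual, sample)
  if (nrow(sites) == 0L) {
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), depth = integer(0),
                      alt_depth = integer(0), stringsAsFactors = FALSE))
  }
  vaf <- true_vaf(individual, spec, sites)
  e <- spec$error_rate %||% 0
  v <- vaf * (1 - e) + (1 - vaf) * e / 3
  set.seed(derive_seed(seed, paste0("reads_", spec$sample_id)))
  depth <- stats::rpois(nrow(sites), spec$target_depth)
  alt_depth <- stats::rbinom(nrow(sites), depth, v)
  data.frame(sample_id = spec$sample_id, chrom = sites$chrom, pos = sites$pos,
             ref = sites$ref, alt = sites$alt, depth = depth,
             alt_depth = alt_depth, stringsAsFactors = FALSE)
}

#' Emit read counts for every sample of an individual
#'
#' @inheritParams true_vaf
#' @param sites data.frame of sites (see [emit_read_counts()]).
#' @param seed Integer seed.
#' @return Row-bound read-count table across all samples.
#' @export
emit_all_read_counts <- function(individual, sites, seed) {
  do.call(rbind, lapply(individual$samples, function(s) {
    emit_read_counts(individual, s, sites, seed)
  }))
}

#' Emit duplex (two-strand) read bundles for one sample
#'
#' Each sampled DNA molecule originates from one cell population and yields
#' one row per strand. A molecule from a carrier population bears the variant
#' on both strands (each read shows it unless hit by an error, probability
#' `1 - e`); non-carrier molecules show the variant on a strand read only
#' through a single-strand error (probability `e / 3` for the specific alt
#' base). Concordant double-strand errors therefore occur at rate
#' `(e / 3)^2` per molecule when one read per strand is taken.
#'
#' @inheritParams true_vaf
#' @param single_strand_error Per-base single-strand error rate in `[0, 1)`.
#' @param seed Integer seed.
#' @param mean_molecules Mean duplex molecules per site (Poisson); defaults
#'   to the sample's `target_depth`.
#' @param reads_per_strand Reads sequenced per strand of each molecule.
#' @return data.frame with `molecule_id, sample_id, chrom, pos, ref, alt,
#'   strand, reads, variant_reads` (two rows per molecule per site).
#' @export
emit_duplex_reads <- function(individual, sample, sites, single_strand_error,
                              seed, mean_molecules = NULL,
                              reads_per_strand = 1L) {
  spec <- get_sample_spec(individual, sample)
  if (single_strand_error < 0 || single_strand_error >= 1) {
    stop("single_strand_error must be in [0, 1)", call. = FALSE)
  }
  mean_molecules <- mean_molecules %||% spec$target_depth
  set.seed(derive_seed(seed, paste0("duplex_", spec$sample_id)))
  n_sites <- nrow(sites)
  n_mol <- stats::rpois(n_sites, mean_molecules)
  total <- sum(n_mol)
  if (total == 0L) {
    return(data.frame(molecule_id = character(0), sample_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      strand = character(0), reads = integer(0),
                      variant_reads = integer(0), stringsAsFactors = FALSE))
  }
  site_of <- rep(seq_len(n_sites), n_mol)
  vaf <- true_vaf(individual, spec, sites)
  # a molecule is a single chromosome copy: carrier probability = allele dosage
  carrier <- stats::runif(total) < vaf[site_of]
  e <- single_strand_error
  mol_idx <- sequence(n_mol)
  mk_strand <- function(strand) {
    vr <- integer(total)
    vr[carrier] <- stats::rbinom(sum(carrier), reads_per_strand, 1 - e)
    vr[!carrier] <- stats::rbinom(sum(!carrier), reads_per_strand, e / 3)
    data.frame(
      molecule_id = paste0(spec$sample_id, ":", site_of, ":", mol_idx),
      sample_id = spec$sample_id,
      chrom = sites$chrom[site_of], pos = sites$pos[site_of],
      ref = sites$ref[site_of], alt = sites$alt[site_of],
      strand = strand, reads = as.integer(reads_per_strand),
      variant_reads = vr, stringsAsFactors = FALSE)
  }
  out <- rbind(mk_strand("+"), mk_strand("-"))
  out[order(out$pos, out$molecule_id, out$strand), , drop = FALSE]
}

#' Sites of the phased-SNP panel of an individual
#' @param individual An `sh_individual`.
#' @return data.frame of `chrom, pos, ref, alt`.
#' @export
snp_sites <- function(individual) {
  individual$snps[, c("chrom", "pos", "ref", "alt")]
}

#' Sites of all simulated somatic mutations (and optionally the germline hit)
#' @param individual An `sh_individual`.
#' @param include_germline Include the germline predisposition variant.
#' @return data.frame of `chrom, pos, ref, alt` (plus `mutation_id` for
#'   somatic rows, NA for the germline row).
#' @export
mutation_sites <- function(individual, include_germline = FALSE) {
  out <- individual$tree$catalog[, c("chrom", "pos", "ref", "alt")]
  out$mutation_id <- individual$tree$catalog$mutation_id
  if (include_germline && !is.null(individual$germline)) {
    g <- individual$germline
    out <- rbind(out, data.frame(chrom = g$chrom, pos = g$pos, ref = g$ref,
                                 alt = g$alt, mutation_id = NA_integer_,
                                 stringsAsFactors = FALSE))
  }
  out
}
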
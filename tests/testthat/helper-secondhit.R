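# shared fixtures, built in code

# down-scaled cohort for module tests: same structure as the default study
# conditions, smaller SNP panel and truncal set
small_cohort_config <- function(n_snps = 200, depth = 30) {
  cfg <- default_cohort_config()
  cfg$snp_panel$n_snps <- n_snps
  cfg$n_truncal <- 100
  cfg$branch_mutation_rate <- 50
  cfg$proband$samples <- lapply(cfg$proband$samples, function(s) {
    if (s$modality == "lcm") s$target_depth <- depth
    s
  })
  cfg
}

# independent tree-traversal oracle: shared mutations of two nodes are the
# branch sets summed over the intersection of their root paths
oracle_shared_count <- function(tree, a, b) {
  pa <- root_path(tree, a)
  pb <- root_path(tree, b)
  common <- intersect(pa, pb)
  sum(lengths(tree$branch_mutations[common]))
}

# toy gene: 3 codons over one exon
toy_gene <- function(cds = "ATGGGGTGG", chrom = "1", start = 1000) {
  gene_model("TOY", cds,
             data.frame(chrom = chrom, start = start,
                        end = start + nchar(cds) - 1,
                        stringsAsFactors = FALSE))
}

# read-count table builder for direct statistical tests
rc_table <- function(sample_id, pos, depth, alt_depth, chrom = "17",
                     ref = "A", alt = "C") {
  data.frame(sample_id = sample_id, chrom = chrom, pos = pos, ref = ref,
             alt = alt, depth = depth, alt_depth = alt_depth,
             stringsAsFactors = FALSE)
}
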
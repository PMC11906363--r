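#' Simulate a somatic lineage tree
#'
#' Generates a random cell-lineage genealogy in which every branch acquires a
#' Poisson number of somatic substitutions. The tree is the ground truth for
#' all downstream inference: a node's somatic genotype is the union of the
#' mutation sets on the branches of its root path, so two descendants share
#' exactly the mutations that accumulated on their common root path.
#'
#' @param n_nodes Number of nodes (>= 1). Node 1 is the root; each later node
#'   attaches to a uniformly chosen earlier node.
#' @param branch_mutation_rate Mean number of substitutions per branch
#'   (Poisson; >= 0). The root carries no branch.
#' @param seed Integer seed; the result is deterministic given
#'   `(n_nodes, branch_mutation_rate, seed)`.
#' @param chroms Chromosome names mutations are scattered over.
#' @param chrom_length Length of each simulated chromosome (bp).
#' @param parents Optional explicit topology: integer vector of parent ids
#'   (NA for the root, which must be node 1, and `parents[i] < i`). When
#'   supplied it overrides the random topology and `n_nodes` must equal its
#'   length; mutation placement stays stochastic.
#'
#' @return An object of class `lineage_tree`: a list with
#'   \describe{
#'     \item{nodes}{data.frame of `node_id`, `parent_id` (NA for the root).}
#'     \item{branch_mutations}{list, per node, of integer mutation ids on the
#'       branch joining it to its parent (empty for the root).}
#'     \item{catalog}{data.frame of `mutation_id, chrom, pos, ref, alt`.}
#'   }
#' @export
simulate_lineage <- function(n_nodes, branch_mutation_rate, seed,
                             chroms = as.character(1:22),
                             chrom_length = 1e8, parents = NULL) {
  if (!is.numeric(n_nodes) || length(n_nodes) != 1L || n_nodes < 1) {
    stop("n_nodes must be a single integer >= 1", call. = FALSE)
  }
  if (!is.numeric(branch_mutation_rate) || branch_mutation_rate < 0) {
    stop("branch_mutation_rate must be >= 0", call. = FALSE)
  }
  n_nodes <- as.integer(n_nodes)
  if (!is.null(parents)) {
    parents <- as.integer(unlist(parents))
    stopifnot(length(parents) == n_nodes, is.na(parents[1]))
    if (n_nodes > 1L && any(is.na(parents[-1]) |
                            parents[-1] >= seq(2L, n_nodes))) {
      stop("parents must be non-NA and precede their children", call. = FALSE)
    }
  }
  set.seed(seed)

  parent <- if (!is.null(parents)) parents else {
    c(NA_integer_,
      if (n_nodes > 1L)
        vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), integer(1)))
  }
  n_mut_branch <- c(0L, if (n_nodes > 1L)
    stats::rpois(n_nodes - 1L, branch_mutation_rate))
  total <- sum(n_mut_branch)

  branch_mutations <- vector("list", n_nodes)
  if (total > 0L) {
    ids <- seq_len(total)
    branch_mutations <- split(ids, rep(seq_len(n_nodes), n_mut_branch))
    branch_mutations <- lapply(as.character(seq_len(n_nodes)),
                               function(k) branch_mutations[[k]] %||% integer(0))
  } else {
    branch_mutations <- replicate(n_nodes, integer(0), simplify = FALSE)
  }

  bases <- c("A", "C", "G", "T")
  ref <- if (total > 0L) sample(bases, total, replace = TRUE) else character(0)
  alt <- if (total > 0L) {
    vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1),
           USE.NAMES = FALSE)
  } else character(0)
  catalog <- data.frame(
    mutation_id = seq_len(total),
    chrom = if (total > 0L) sample(chroms, total, replace = TRUE) else character(0),
    pos = if (total > 0L) sample.int(chrom_length, total, replace = TRUE) else integer(0),
    ref = ref, alt = alt,
    stringsAsFactors = FALSE
  )

  structure(
    list(nodes = data.frame(node_id = seq_len(n_nodes), parent_id = parent),
         branch_mutations = branch_mutations,
         catalog = catalog),
    class = "lineage_tree"
  )
}

#' Path from a node to the root
#' @param tree A `lineage_tree`.
#' @param node_id Node to trace.
#' @return Integer vector of node ids from `node_id` up to and including the root.
#' @export
root_path <- function(tree, node_id) {
  parent <- tree$nodes$parent_id
  path <- integer(0)
  i <- as.integer(node_id)
  while (!is.na(i)) {
    path <- c(path, i)
    i <- parent[i]
  }
  path
}

#' Somatic genotype of a node
#'
#' The union of branch mutation sets along the node's root path.
#'
#' @inheritParams root_path
#' @return Sorted integer vector of mutation ids.
#' @export
node_genotype <- function(tree, node_id) {
  sort(unique(unlist(tree$branch_mutations[root_path(tree, node_id)])))
}

#' Mutations shared by two nodes through common ancestry
#'
#' @inheritParams root_path
#' @param node_a,node_b Node ids.
#' @return Sorted integer vector of mutation ids present in both genotypes.
#' @export
shared_mutations <- function(tree, node_a, node_b) {
  intersect(node_genotype(tree, node_a), node_genotype(tree, node_b))
}

#' @export
print.lineage_tree <- function(x, ...) {
  cat(sprintf("<lineage_tree> %d nodes, %d somatic mutations\n",
              nrow(x$nodes), nrow(x$catalog)))
  invisible(x)
}
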
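# Shared fixtures and independent oracles used across the suite.

# Three-taxon tree with known shared branch lengths.
tree_abc <- function() read_trees("((A:1,B:1):1,C:2);")[[1]]

# Star tree: no shared history, all tips at depth `t`.
star_tree <- function(n, depth = 1) {
  labs <- paste0("t", seq_len(n))
  read_trees(paste0("(", paste0(labs, ":", depth, collapse = ","), ");"))[[1]]
}

# Independent Brownian-VCV oracle: walks the edge table and sums the branch
# lengths shared by each pair of root-to-tip paths. Deliberately avoids
# ape::vcv.phylo, which the implementation wraps.
oracle_vcv <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  parent <- integer(max(tree$edge))
  elen <- numeric(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  elen[tree$edge[, 2]] <- tree$edge.length
  path_nodes <- function(tip) {
    out <- integer(0)
    node <- tip
    while (node != root) {
      out <- c(out, node)
      node <- parent[node]
    }
    out
  }
  paths <- lapply(seq_len(n), path_nodes)
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
    }
  }
  C
}

# Apply Pagel's lambda to a plain covariance matrix (kept inline so oracle
# computations do not depend on package internals).
shrink_offdiag <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Random DAG on k nodes, acyclic by construction (edges only i -> j, i < j).
random_dag <- function(k, p_edge = 0.4) {
  nodes <- paste0("n", seq_len(k))
  from <- character(0)
  to <- character(0)
  for (i in seq_len(k - 1)) {
    for (j in seq((i + 1), k)) {
      if (stats::runif(1) < p_edge) {
        from <- c(from, nodes[i])
        to <- c(to, nodes[j])
      }
    }
  }
  causal_model("random", nodes, cbind(from = from, to = to))
}

# Convenience: simulate one comparative dataset and its first tree's VCV.
quick_sim <- function(seed, ...) {
  sim <- simulate_dataset(simulation_config(seed = seed, ...))
  sim$pc <- brownian_vcv(sim$trees[[1]])
  sim
}
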
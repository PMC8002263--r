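# Shared fixtures, built in code.

# A small but non-trivial architecture used wherever the full default
# (depth 4, 16..256 channels) would be needlessly slow.
tiny_net <- function(block = "se_residual") {
  network_config(depth = 2L, channels = c(4L, 6L, 8L), block = block)
}

# Short, well-separated synthetic cohort: artefact rates on so the filters
# always have work to do.
tiny_cohort <- function(n_per_class = 4, n_beats = 600, seed = 101) {
  generate_cohort(n_per_class = n_per_class, n_beats = n_beats, seed = seed)
}

tiny_dataset <- function(n = 64, depth = 2, ...) {
  build_dataset(tiny_cohort(...), n = n, depth = depth)
}

# Independent brute-force enumeration of the node lattice: every node
# X(i, j) with i + j <= L; its dependency set straight from the recurrence
# (down edge for j = 0, j skips plus one up edge for j > 0).
enumerate_grid <- function(L) {
  nodes <- list(); edges <- list()
  for (i in 0:L) for (j in 0:(L - i)) {
    nodes[[length(nodes) + 1]] <- c(i = i, j = j)
    if (j == 0 && i > 0) {
      edges[[length(edges) + 1]] <- c(i - 1, 0, i, j)
    } else if (j > 0) {
      for (k in 0:(j - 1)) edges[[length(edges) + 1]] <- c(i, k, i, j)
      edges[[length(edges) + 1]] <- c(i + 1, j - 1, i, j)
    }
  }
  list(nodes = do.call(rbind, nodes), edges = do.call(rbind, edges))
}

# Exhaustive positive-negative pair counting: the rank-statistic AUC oracle.
auc_pairwise <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) wins <- wins + sum(p > neg) + 0.5 * sum(p == neg)
  wins / (length(pos) * length(neg))
}
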
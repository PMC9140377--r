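# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# exhaustive minimum-change score over all internal-node assignments
# (5 states: A, C, G, T, gap), for small rooted trees
oracle_parsimony_score <- function(tree, leaf_states) {
  states <- c("A", "C", "G", "T", "-")
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  stopifnot(length(leaf_states) == ntip)
  grid <- do.call(expand.grid,
                  c(rep(list(states), nnode), stringsAsFactors = FALSE))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(leaf_states, unlist(grid[r, ], use.names = FALSE))
    changes <- sum(assign_all[tree$edge[, 1]] != assign_all[tree$edge[, 2]])
    if (changes < best) best <- changes
  }
  best
}

# one-sided Fisher p (alternative: odds ratio > 1) by direct hypergeometric
# tail summation with log-binomials
oracle_fisher_greater <- function(a, b, c, d) {
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  denom <- lchoose(m + n, k)
  ks <- a:hi
  sum(exp(lchoose(m, ks) + lchoose(n, k - ks) - denom))
}

# path length between two nodes by breadth-first walk over the adjacency list
oracle_path_length <- function(tree, a, b) {
  nn <- ape::Ntip(tree) + tree$Nnode
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    i <- tree$edge[e, 1]; j <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[i]] <- rbind(adj[[i]], c(j, w))
    adj[[j]] <- rbind(adj[[j]], c(i, w))
  }
  dist <- rep(NA_real_, nn)
  dist[a] <- 0
  queue <- a
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (r in seq_len(NROW(adj[[v]]))) {
      u <- adj[[v]][r, 1]
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + adj[[v]][r, 2]
        queue <- c(queue, u)
      }
    }
  }
  dist[b]
}

# a random rooted ultrametric-free tree with strictly positive branch lengths
random_additive_tree <- function(ntaxa) {
  tr <- ape::rtree(ntaxa)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.02, 0.5)
  tr
}

# random nucleotide string
random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = "")

# tiny scenario for fast tests
small_scenario <- function(L = 900L, seed = 1L, ...) {
  ps5_scenario(seed = seed, sequence_length = as.integer(L), ...)
}
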
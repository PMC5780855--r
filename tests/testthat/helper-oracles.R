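# Independent oracles used across the test suite.  These deliberately do
# not reuse the package's matching / reachability / ILP code paths.

# Brute-force maximum matching size of a bipartite graph given as a list
# of candidate left-node vectors, one per right node.  Pure recursion.
bf_matching_size <- function(adj) {
  recurse <- function(i, used) {
    if (i > length(adj)) return(0L)
    best <- recurse(i + 1L, used)  # leave right node i unmatched
    for (u in adj[[i]]) {
      if (!u %in% used) {
        best <- max(best, 1L + recurse(i + 1L, c(used, u)))
      }
    }
    best
  }
  recurse(1L, character(0))
}

# adjacency (right -> left candidates) of the bipartite representation a
# level encodes, recomputed directly from the network edge list
bf_level_adj <- function(network, right) {
  en <- edge_names(network)
  lapply(right, function(r) unique(en[en[, 2] == r, 1]))
}

# graph reachability by BFS on the character edge list
bf_reachable <- function(network, start) {
  en <- edge_names(network)
  seen <- character(0)
  frontier <- start
  repeat {
    nxt <- setdiff(unique(en[en[, 1] %in% frontier, 2]), c(seen, start))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# exhaustive minimum of W = 2|D| - |D n Q| over all covers, written
# independently of the package's bitmask oracle (plain subset recursion)
bf_min_cover_weight <- function(families, q) {
  cand <- sort(unique(unlist(families)))
  best <- Inf
  k <- length(cand)
  for (s in 0:(2^k - 1)) {
    d <- cand[bitwAnd(bitwShiftR(s, seq_len(k) - 1L), 1L) == 1L]
    if (all(vapply(families, function(f) any(f %in% d), TRUE))) {
      w <- 2L * length(d) - length(intersect(d, q))
      if (w < best) best <- w
    }
  }
  best
}

# small random directed network plus random nonempty target subset
random_instance <- function(seed, n_max = 12L, q_frac = 0.4) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  l <- sample(n:(3 * n), 1)
  net <- synthetic_network("erdos_renyi", n = n, l = min(l, n^2),
                           seed = seed + 1000L)
  o <- sample(net$nodes, sample(1:max(1, n %/% 2), 1))
  q <- sample(net$nodes, max(1L, round(q_frac * n)))
  list(network = net, targets = o, constraints = q)
}

# write the toy fixture to disk for CLI tests; returns the three paths
write_toy_files <- function(dir = withr::local_tempdir(
                              .local_envir = parent.frame())) {
  toy <- toy_fixture()
  net_path <- file.path(dir, "toy.tsv")
  write_edge_list(toy$network, net_path)
  o_path <- file.path(dir, "targets.txt")
  writeLines(as.character(toy$targets), o_path)
  q_path <- file.path(dir, "constraints.txt")
  writeLines(as.character(toy$constraints), q_path)
  list(network = net_path, targets = o_path, constraints = q_path,
       dir = dir)
}

# the documented level matchings of the six-node worked example
toy_printed_matchings <- function() {
  list(list(c("v2", "v3"), c("v3", "v4"), c("v5", "v6")),
       list(c("v1", "v3"), c("v3", "v5")),
       list(c("v1", "v3")))
}
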
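#' Generate a synthetic directed network
#'
#' Reproducible random test networks standing in for real interactome
#' downloads.  Two models are provided:
#'
#' * `"erdos_renyi"`: exactly `l` directed edges sampled uniformly without
#'   replacement from all `n^2` ordered pairs (self-loops included);
#' * `"scale_free"`: a static-fitness graph
#'   ([igraph::sample_fitness_pl()]) whose in- and out-degree
#'   distributions follow power laws with the requested exponents.
#'
#' Both are bit-reproducible under a fixed `seed`; the caller's RNG state
#' is left untouched.
#'
#' @param model `"erdos_renyi"` or `"scale_free"`.
#' @param n number of nodes (>= 1); nodes are named `n1 ... n<n>`.
#' @param l number of edges.  For `"erdos_renyi"` this is exact and must not
#'   exceed `n^2`; for `"scale_free"` it is the expected edge budget passed
#'   to the fitness model (self-loops and multi-edges are excluded there, so
#'   the realised count can be slightly smaller).
#' @param exponent_out,exponent_in power-law exponents for the scale-free
#'   model (defaults 2.5, a typical value for biological interactomes).
#' @param seed integer seed.
#' @return a [directed_network()].
#' @examples
#' net <- synthetic_network("erdos_renyi", n = 20, l = 40, seed = 1)
#' network_size(net)
#' @export
synthetic_network <- function(model = c("erdos_renyi", "scale_free"),
                              n, l, exponent_out = 2.5, exponent_in = 2.5,
                              seed = 1) {
  model <- match.arg(model)
  n <- as.integer(n)
  l <- as.integer(l)
  if (n < 1) stop_usage("n must be >= 1")
  nodes <- paste0("n", seq_len(n))
  if (model == "erdos_renyi") {
    if (l > n^2) stop_usage("requested ", l, " edges but only ", n^2,
                            " ordered pairs exist")
    em <- with_seed(seed, {
      idx <- sample.int(n^2, l)
      cbind(nodes[((idx - 1L) %/% n) + 1L], nodes[((idx - 1L) %% n) + 1L])
    })
  } else {
    g <- with_seed(seed, igraph::sample_fitness_pl(
      no.of.nodes = n, no.of.edges = l,
      exponent.out = exponent_out, exponent.in = exponent_in,
      loops = FALSE, multiple = FALSE, finite.size.correction = FALSE))
    el <- igraph::as_edgelist(g, names = FALSE)
    em <- cbind(nodes[el[, 1]], nodes[el[, 2]])
  }
  suppressMessages(directed_network(em, nodes = nodes))
}

#' The six-node worked-example network
#'
#' A small directed network used throughout the documentation and tests:
#' nodes `v1..v6`, edges v1->v3, v2->v3, v4->v3, v3->v4, v3->v5, v4->v5,
#' v5->v6; target set \eqn{O = \{v3, v4, v6\}} and constraint set
#' \eqn{Q = \{v1\}}.  Placing a single input on v1 suffices to steer all
#' three targets, while classical full-network control needs two inputs.
#' The edge v4->v5 is a reconstruction: it is chosen so that the
#' full-control analysis of this network requires exactly two driver nodes
#' while every documented level matching of the iterated bipartite
#' construction is preserved; all other worked-example quantities are
#' insensitive to it.
#'
#' @return a list with elements `network` ([directed_network()]),
#'   `targets` and `constraints` (both [node_subset()]).
#' @examples
#' toy <- toy_fixture()
#' toy$network
#' @export
toy_fixture <- function() {
  edges <- rbind(c("v1", "v3"), c("v2", "v3"), c("v4", "v3"),
                 c("v3", "v4"), c("v3", "v5"), c("v4", "v5"),
                 c("v5", "v6"))
  net <- directed_network(edges, nodes = paste0("v", 1:6))
  list(network = net,
       targets = node_subset(c("v3", "v4", "v6"), net, role = "target"),
       constraints = node_subset("v1", net, role = "constraint"))
}

# igraph view of a directed_network (used by evaluation statistics)
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    as.data.frame(edge_names(network), stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = network$nodes, stringsAsFactors = FALSE))
}
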
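# Target control tree (TCT): a leveled directed graph recording which
# upstream nodes control which downstream nodes, built from the per-level
# maximum matchings of the linking and dynamic graph.
#
# Within a level, matched pairs chain: if u is matched to w and w is itself
# matched (as a left node of the same level) to z, then u also gains the
# edge (u, z).  Chained pairs are what make the TCT strictly richer than
# the matching: its edges need not be network edges.

#' Build the target control tree
#'
#' For every level \eqn{n} of the linking and dynamic graph, the level edge
#' set \eqn{E_n} contains \eqn{(u, w)} exactly when \eqn{w} is reachable
#' from \eqn{u} by chaining matched pairs within that level's matching
#' (a direct matched pair is the chain of length one).  Since each node has
#' at most one outgoing matched pair per level, chains are simple paths (or
#' cycles, which are truncated on revisit).
#'
#' @param ldg a `linking_dynamic_graph`.
#' @return an object of class `target_control_tree`: per-level edge sets
#'   `level_edges` (named `E0`, `E1`, ...), their deduplicated union
#'   `edges`, and a successor adjacency list over the union.
#' @examples
#' toy <- toy_fixture()
#' ldg <- build_linking_dynamic_graph(toy$network, toy$targets, seed = 1)
#' build_target_control_tree(ldg)
#' @export
build_target_control_tree <- function(ldg) {
  n <- length(ldg$nodes)
  level_edges <- list()
  for (rec in ldg$levels) {
    m <- rec$matching
    em <- matrix(integer(0), ncol = 2)
    for (u in m$pairs[, 1L]) {
      z <- m$mL[u]
      visited <- c(u)
      while (z != 0L && !(z %in% visited)) {
        if (z != u) em <- rbind(em, c(u, z))
        visited <- c(visited, z)
        z <- m$mL[z]
      }
    }
    em <- em[!duplicated(paste(em[, 1], em[, 2])), , drop = FALSE]
    colnames(em) <- c("from", "to")
    level_edges[[paste0("E", rec$level$index)]] <- em
  }
  all_e <- do.call(rbind, level_edges)
  if (is.null(all_e)) all_e <- matrix(integer(0), ncol = 2,
                                      dimnames = list(NULL, c("from", "to")))
  all_e <- all_e[!duplicated(paste(all_e[, 1], all_e[, 2])), , drop = FALSE]
  succ <- unname(split(all_e[, 2], factor(all_e[, 1], levels = seq_len(n))))
  structure(list(level_edges = level_edges, edges = all_e, succ = succ,
                 nodes = ldg$nodes),
            class = "target_control_tree")
}

#' @export
print.target_control_tree <- function(x, ...) {
  cat("Target control tree:", nrow(x$edges), "edge(s) over",
      length(x$level_edges), "level(s)\n")
  for (nm in names(x$level_edges)) {
    em <- x$level_edges[[nm]]
    if (nrow(em)) {
      cat("  ", nm, ": ",
          paste0("(", x$nodes[em[, 1]], ",", x$nodes[em[, 2]], ")",
                 collapse = " "), "\n", sep = "")
    } else {
      cat("  ", nm, ": (empty)\n", sep = "")
    }
  }
  invisible(x)
}

#' Level edge sets of a target control tree, by node name
#'
#' @param tct a `target_control_tree`.
#' @return a named list of two-column character matrices, one per level.
#' @export
tct_level_edges <- function(tct) {
  lapply(tct$level_edges, function(em) {
    matrix(tct$nodes[em], ncol = 2, dimnames = list(NULL, c("from", "to")))
  })
}

#' Export a target control tree as an edge list with a level column
#'
#' @param tct a `target_control_tree`.
#' @return a data frame with columns `from`, `to`, `level`.
#' @export
tct_edge_list <- function(tct) {
  rows <- lapply(names(tct$level_edges), function(nm) {
    em <- tct$level_edges[[nm]]
    if (!nrow(em)) return(NULL)
    data.frame(from = tct$nodes[em[, 1]], to = tct$nodes[em[, 2]],
               level = as.integer(sub("^E", "", nm)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(from = character(0), to = character(0),
                                      level = integer(0))
  out
}

# BFS over the flat TCT union from a single start node (integer id);
# returns the set of reached ids (start excluded).
tct_reach <- function(tct, start) {
  n <- length(tct$nodes)
  seen <- logical(n)
  frontier <- start
  reached <- integer(0)
  while (length(frontier)) {
    nxt <- unique(unlist(tct$succ[frontier]))
    nxt <- nxt[!seen[nxt]]
    if (!length(nxt)) break
    seen[nxt] <- TRUE
    reached <- c(reached, nxt)
    frontier <- nxt
  }
  reached
}

#' Controllable target subspace of a node
#'
#' Breadth-first reachability over the target control tree (treated as one
#' flat directed graph across levels): TCS(v) is the set of target nodes
#' reachable from v, with v itself included when v is a target — a direct
#' input column on a target trivially controls it.
#'
#' @param tct a `target_control_tree`.
#' @param node a single node identifier.
#' @param targets the target set \eqn{O}.
#' @return sorted character vector, a subset of the targets.
#' @export
controllable_subspace <- function(tct, node, targets) {
  targets <- as_members(targets)
  net <- structure(list(nodes = tct$nodes), class = "directed_network")
  id <- node_index(net, node)
  reached <- tct$nodes[tct_reach(tct, id)]
  out <- intersect(reached, targets)
  if (node %in% targets) out <- union(out, node)
  sort(out)
}

#' Controllable subspaces of all nodes, with covering families
#'
#' Computes TCS(v) for every network node and the dual families
#' \eqn{F_u = \{v : u \in TCS(v)\}} for every target \eqn{u}: the nodes on
#' which a single input steers \eqn{u}.  Exact duality
#' \eqn{u \in TCS(v) \iff v \in F_u} holds by construction.
#'
#' @param tct a `target_control_tree`.
#' @param network the source [directed_network()].
#' @param targets the target set \eqn{O}.
#' @return an object of class `tcs_map`: named lists `tcs` (per node) and
#'   `families` (per target).
#' @export
controllable_subspace_map <- function(tct, network, targets) {
  targets <- as_members(targets)
  node_index(network, targets, what = "target")
  tcs <- lapply(network$nodes, function(v)
    controllable_subspace(tct, v, targets))
  names(tcs) <- network$nodes
  families <- lapply(targets, function(u)
    sort(network$nodes[vapply(tcs, function(s) u %in% s, FALSE)]))
  names(families) <- targets
  structure(list(tcs = tcs, families = families, targets = targets),
            class = "tcs_map")
}

#' @export
print.tcs_map <- function(x, ...) {
  nonempty <- sum(lengths(x$tcs) > 0)
  cat("Controllable subspace map:", length(x$tcs), "nodes (", nonempty,
      "with nonempty TCS ),", length(x$targets), "targets\n")
  invisible(x)
}

#' Per-target covering families
#'
#' Extracts \eqn{F_u} for each target and flags targets with an empty
#' family as uncoverable.  (With target self-inclusion every target covers
#' itself, so uncoverable targets can only arise for families assembled by
#' other means.)
#'
#' @param tcs_map a `tcs_map` from [controllable_subspace_map()].
#' @return a list with `families` (named list of character vectors) and
#'   `uncoverable` (character vector of targets with empty families).
#' @export
covering_families <- function(tcs_map) {
  fam <- tcs_map$families
  list(families = fam,
       uncoverable = names(fam)[lengths(fam) == 0])
}
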
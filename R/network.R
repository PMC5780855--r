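#' Construct a directed network
#'
#' The basic container for a directed graph \eqn{G(V, E)}: a set of node
#' identifiers and a set of ordered edges.  Node identifiers are opaque,
#' case-sensitive strings; duplicate edges are collapsed (with a message
#' giving the count) and self-loops are permitted.  The adjacency structure
#' is all that downstream controllability analysis needs: an edge
#' \eqn{u \to v} marks a nonzero entry at row \eqn{v}, column \eqn{u} of the
#' state matrix \eqn{A} in the linearised dynamics \eqn{dx/dt = Ax + Bu}.
#'
#' @param edges a two-column character matrix or data frame (source, target),
#'   or `NULL` for an edgeless network.
#' @param nodes optional character vector of node identifiers; the node set
#'   is the union of `nodes` and all edge endpoints, so isolated nodes can
#'   be declared here.
#' @return an object of class `directed_network` with elements `nodes`
#'   (character vector), `edges` (integer matrix of node indices, columns
#'   `from`/`to`), and predecessor/successor adjacency lists.
#' @examples
#' net <- directed_network(cbind(c("a", "b"), c("b", "c")))
#' net
#' @export
directed_network <- function(edges = NULL, nodes = NULL) {
  if (is.null(edges)) {
    em <- matrix(character(0), ncol = 2)
  } else {
    em <- as.matrix(edges)
    if (ncol(em) != 2) stop_usage("edges must have exactly two columns")
    storage.mode(em) <- "character"
  }
  if (nrow(em)) {
    dup <- duplicated(paste(em[, 1], em[, 2], sep = "\r"))
    if (any(dup)) {
      message(sum(dup), " duplicate edge(s) collapsed")
      em <- em[!dup, , drop = FALSE]
    }
  }
  all_nodes <- sort(unique(c(as.character(nodes %||% character(0)),
                             em[, 1], em[, 2])))
  n <- length(all_nodes)
  ie <- matrix(match(em, all_nodes), ncol = 2,
               dimnames = list(NULL, c("from", "to")))
  pred <- unname(split(ie[, 1], factor(ie[, 2], levels = seq_len(n))))
  succ <- unname(split(ie[, 2], factor(ie[, 1], levels = seq_len(n))))
  structure(list(nodes = all_nodes, edges = ie, pred = pred, succ = succ),
            class = "directed_network")
}

#' @export
print.directed_network <- function(x, ...) {
  cat("Directed network:", length(x$nodes), "nodes,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

# number of nodes / edges
#' @export
#' @rdname directed_network
#' @param x,network a `directed_network`
network_size <- function(network) {
  c(N = length(network$nodes), L = nrow(network$edges))
}

# map node names -> integer indices, failing loudly on unknown names
node_index <- function(network, names, what = "node") {
  idx <- match(names, network$nodes)
  if (anyNA(idx)) {
    stop_usage("unknown ", what, "(s): ",
               paste(names[is.na(idx)], collapse = ", "))
  }
  idx
}

# character edge list view (n x 2)
edge_names <- function(network) {
  matrix(network$nodes[network$edges], ncol = 2,
         dimnames = list(NULL, c("from", "to")))
}

#' Bind a set of node identifiers to a network role
#'
#' A `node_subset` tags a deduplicated set of node identifiers with the role
#' it plays in a target-control analysis: the target set \eqn{O} (nodes whose
#' state must be steered), the constraint set \eqn{Q} (preferred drivers,
#' e.g. approved drug targets), a driver set \eqn{D}, or a generic set.
#' When a network is supplied, membership is enforced.
#'
#' @param members character vector of node identifiers (duplicates dropped).
#' @param network optional `directed_network`; if given, members must belong
#'   to it.
#' @param role one of `"generic"`, `"target"`, `"constraint"`, `"driver"`.
#' @return character vector of class `node_subset` with a `role` attribute.
#' @export
node_subset <- function(members, network = NULL,
                        role = c("generic", "target", "constraint", "driver")) {
  role <- match.arg(role)
  members <- unique(as.character(members))
  if (!is.null(network)) node_index(network, members)
  structure(members, role = role, class = "node_subset")
}

#' @export
print.node_subset <- function(x, ...) {
  cat("Node subset (role: ", attr(x, "role"), "): ", length(x),
      " member(s)\n", sep = "")
  if (length(x)) cat(" ", paste(utils::head(x, 20), collapse = ", "),
                     if (length(x) > 20) "...", "\n")
  invisible(x)
}

as_members <- function(x) {
  if (is.null(x)) character(0) else unique(as.character(x))
}

#' Read a directed edge list from a text file
#'
#' One edge per line, at least two fields (source, target).  A third field
#' equal to `"u"` flags the edge as undirected; both orientations are added.
#' Lines starting with `#` and blank lines are skipped; LF and CRLF endings
#' and UTF-8 identifiers are accepted.  Duplicate edges are collapsed.
#'
#' @param path path to the file.
#' @param dialect field separator: `"tab"`, `"whitespace"`, or `"csv"`.
#' @return a [directed_network()].
#' @export
read_edge_list <- function(path, dialect = c("tab", "whitespace", "csv")) {
  dialect <- match.arg(dialect)
  if (!is.character(path) || length(path) != 1 || !nzchar(path) ||
      !file.exists(path)) {
    stop_io("cannot read edge list: no such file: '",
            paste(path, collapse = ""), "'")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (!length(idx)) return(directed_network())
  sep <- switch(dialect, tab = "\t", whitespace = "[ \t]+", csv = ",")
  parts <- strsplit(lines[idx], sep, perl = TRUE)
  nf <- lengths(parts)
  if (any(nf < 2)) {
    bad <- idx[which(nf < 2)[1]]
    stop_io("malformed edge list line ", bad, " in '", path,
            "': fewer than 2 fields")
  }
  from <- trimws(vapply(parts, `[`, "", 1L))
  to <- trimws(vapply(parts, `[`, "", 2L))
  flag <- trimws(vapply(parts, function(p) if (length(p) >= 3) p[3] else "",
                        ""))
  net <- directed_network(cbind(from, to))
  undirected <- flag %in% c("u", "U")
  if (any(undirected)) {
    net <- expand_mixed_edges(net, cbind(from[undirected], to[undirected]))
  }
  net
}

#' Read a node list and bind it to a network
#'
#' One identifier per line; duplicates are dropped.  Identifiers absent from
#' the network are reported (as a message and in the `off_network`
#' attribute) but are not an error: curated gene lists routinely contain
#' entries outside a given interaction network.
#'
#' @param path path to the file.
#' @param network a `directed_network` the identifiers are matched against.
#' @param role role tag passed to [node_subset()].
#' @return a [node_subset()] of the in-network members, with attribute
#'   `off_network` holding the identifiers that were not found.
#' @export
read_node_list <- function(path, network,
                           role = c("generic", "target", "constraint",
                                    "driver")) {
  role <- match.arg(role)
  if (!is.character(path) || length(path) != 1 || !nzchar(path) ||
      !file.exists(path)) {
    stop_io("cannot read node list: no such file: '",
            paste(path, collapse = ""), "'")
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  ids <- unique(lines)
  present <- ids %in% network$nodes
  if (any(!present)) {
    message(sum(!present), " identifier(s) not in the network")
  }
  out <- node_subset(ids[present], network, role = role)
  attr(out, "off_network") <- ids[!present]
  out
}

#' Expand undirected edges into both orientations
#'
#' Case-study networks mix directed and undirected (bi-directed)
#' interactions; each undirected pair \{a, b\} contributes both a -> b and
#' b -> a.  Directed edges are untouched and the operation is idempotent.
#'
#' @param network a `directed_network`.
#' @param undirected_pairs two-column character matrix of unordered pairs;
#'   endpoints must exist in the network.
#' @return a `directed_network` with both orientations present.
#' @export
expand_mixed_edges <- function(network, undirected_pairs) {
  up <- as.matrix(undirected_pairs)
  if (!nrow(up)) return(network)
  if (ncol(up) != 2) stop_usage("undirected_pairs must have two columns")
  storage.mode(up) <- "character"
  node_index(network, unique(c(up)), what = "endpoint")
  new_edges <- rbind(edge_names(network), up, up[, 2:1, drop = FALSE])
  suppressMessages(directed_network(new_edges, nodes = network$nodes))
}

#' Write a network as an edge list
#'
#' @param network a `directed_network`.
#' @param path output file path.
#' @param dialect field separator, as in [read_edge_list()].
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(network, path,
                            dialect = c("tab", "whitespace", "csv")) {
  dialect <- match.arg(dialect)
  sep <- switch(dialect, tab = "\t", whitespace = " ", csv = ",")
  en <- edge_names(network)
  writeLines(paste(en[, 1], en[, 2], sep = sep), path, useBytes = TRUE)
  invisible(path)
}
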
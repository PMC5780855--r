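# Iterated bipartite matching: the "linking and dynamic graph".
#
# Level n is a bipartite graph B_n = (L_n, R_n): R_0 is the target set,
# L_n the direct predecessors of R_n, and the links are the network edges
# into R_n.  Level n >= 1 takes as its right side the *matched* left nodes
# of the previous level's maximum matching.  A node may sit on both sides
# of a level (e.g. a target that also feeds another target); roles are kept
# separate.  Restricting the left side to direct predecessors is lossless:
# an ancestor without a direct edge into R_n contributes no link and could
# never be matched.

# ---- levels -----------------------------------------------------------

new_level <- function(network, right, index) {
  adj <- network$pred[right]
  left <- sort(unique(unlist(adj)))
  links <- if (length(right)) {
    cbind(from = unlist(adj),
          to = rep(right, lengths(adj)))
  } else {
    matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  structure(list(index = index, right = right, left = left, adj = adj,
                 nodes = network$nodes),
            class = "bipartite_level")
}

#' @export
print.bipartite_level <- function(x, ...) {
  cat("Bipartite level B_", x$index, ": |R| = ", length(x$right),
      ", |L| = ", length(x$left), ", ", sum(lengths(x$adj)), " links\n",
      sep = "")
  invisible(x)
}

#' Build the initial bipartite level for a target set
#'
#' Level \eqn{B_0}: the right side is the target set \eqn{O}, the left side
#' the direct predecessors of any target, and the links are the network
#' edges into targets.  Self-loops are allowed and a target may appear on
#' both sides.
#'
#' @param network a [directed_network()].
#' @param targets a [node_subset()] or character vector of target nodes
#'   (nonempty, all in the network).
#' @return an object of class `bipartite_level` with fields `index`,
#'   `right`, `left` (integer node indices) and the per-right-node
#'   adjacency `adj`.
#' @export
build_initial_level <- function(network, targets) {
  t_ids <- node_index(network, as_members(targets), what = "target")
  if (!length(t_ids)) stop_usage("target set must be nonempty")
  new_level(network, sort(t_ids), index = 0L)
}

#' Links of a bipartite level as a character edge matrix
#'
#' @param level a `bipartite_level`.
#' @return two-column character matrix (left node, right node).
#' @export
level_links <- function(level) {
  ln <- cbind(rep(level$right, lengths(level$adj)))
  matrix(level$nodes[cbind(unlist(level$adj), ln)], ncol = 2,
         dimnames = list(NULL, c("left", "right")))
}

# ---- maximum matching (randomized Kuhn augmenting paths) --------------

# Internal workhorse: maximum matching of a level using depth-first
# augmenting paths.  The visiting order of right nodes and of each
# adjacency list is randomized from the current RNG stream, so different
# streams can realise different maximum matchings of the same (invariant)
# cardinality -- this degeneracy is the MCMC state space.
#
# forbid: optional c(left, right) link that must not be used.
kuhn_matching <- function(level, forbid = NULL) {
  n <- length(level$nodes)
  mL <- integer(n)  # left node  -> matched right node (0 = unmatched)
  mR <- integer(n)  # right node -> matched left node
  right <- level$right
  pos <- integer(n)
  pos[right] <- seq_along(right)
  adj <- level$adj
  if (!is.null(forbid)) {
    p <- pos[forbid[2L]]
    if (p > 0L) adj[[p]] <- adj[[p]][adj[[p]] != forbid[1L]]
  }
  adj <- lapply(adj, sample_vec)
  visited <- logical(n)
  augment <- function(ri) {
    for (u in adj[[ri]]) {
      if (!visited[u]) {
        visited[u] <<- TRUE
        r2 <- mL[u]
        if (r2 == 0L || augment(pos[r2])) {
          mL[u] <<- right[ri]
          mR[right[ri]] <<- u
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (ri in sample_vec(seq_along(right))) {
    visited[] <- FALSE
    augment(ri)
  }
  matched_r <- right[mR[right] != 0L]
  pairs <- cbind(left = mR[matched_r], right = matched_r)
  structure(list(pairs = pairs, mL = mL, mR = mR, size = nrow(pairs),
                 nodes = level$nodes),
            class = "matching")
}

#' @export
print.matching <- function(x, ...) {
  cat("Matching of size", x$size, "\n")
  if (x$size) {
    p <- matching_pairs(x)
    cat(paste0("  (", p[, 1], ", ", p[, 2], ")", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Matched pairs as a character matrix
#' @param matching a `matching`.
#' @return two-column character matrix (left, right).
#' @export
matching_pairs <- function(matching) {
  matrix(matching$nodes[matching$pairs], ncol = 2,
         dimnames = list(NULL, c("left", "right")))
}

#' Maximum matching of a bipartite level
#'
#' Depth-first augmenting-path search with randomized visiting order.  The
#' cardinality of the result is the maximum for the level regardless of the
#' seed; the *composition* may differ between seeds, which is deliberate:
#' the set of maximum matchings is the state space later sampled by the
#' Markov chain.
#'
#' @param level a `bipartite_level`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return an object of class `matching`: matched `pairs` (integer indices),
#'   per-node partner maps and the matching `size`.
#' @export
maximum_matching <- function(level, seed = NULL) {
  with_seed(seed, kuhn_matching(level))
}

# canonical key of an (R_n, matching support) state, for repeat detection
chain_key <- function(right, matching) {
  p <- matching$pairs
  o <- order(p[, 2])
  paste(paste(right, collapse = ","),
        paste(p[o, 1], p[o, 2], sep = "-", collapse = ","), sep = "|")
}

# Extend a list of (level, matching) records downward until the left side
# empties, an (R_n, m_n) state repeats, or the level cap is reached.
# `seen` is the set of keys of the retained levels.
extend_ldg <- function(network, records, seen, cap) {
  repeat {
    last <- records[[length(records)]]
    right_n <- sort(unique(last$matching$pairs[, 1L]))
    if (!length(right_n)) return(list(records = records, seen = seen,
                                      termination = "empty_left"))
    lev <- new_level(network, right_n, index = last$level$index + 1L)
    if (!length(lev$left)) return(list(records = records, seen = seen,
                                       termination = "empty_left"))
    if (length(records) >= cap) {
      return(list(records = records, seen = seen,
                  termination = "cap_reached"))
    }
    m <- kuhn_matching(lev)
    key <- chain_key(right_n, m)
    if (key %in% seen) {
      return(list(records = records, seen = seen,
                  termination = "repeat_detected"))
    }
    seen <- c(seen, key)
    records[[length(records) + 1L]] <- list(level = lev, matching = m)
  }
}

new_ldg <- function(records, seen, termination, network) {
  structure(list(levels = records, seen = seen, termination = termination,
                 r = length(records), nodes = network$nodes),
            class = "linking_dynamic_graph")
}

#' Build the linking and dynamic graph
#'
#' The iterated bipartite construction: level 0 is
#' [build_initial_level()]; thereafter the right side of level \eqn{n} is
#' the set of *matched* left nodes of level \eqn{n-1}'s maximum matching.
#' Iteration stops when the left side is empty, when an
#' \eqn{(R_n, m_n)} state repeats (which happens in cyclic networks), or
#' after \eqn{N} levels, whichever comes first, so the build terminates on
#' every finite network.
#'
#' @param network a [directed_network()].
#' @param targets target [node_subset()] or character vector.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @return an object of class `linking_dynamic_graph`: `levels` (a list of
#'   `list(level, matching)` records), the `termination` reason
#'   (`"empty_left"`, `"repeat_detected"` or `"cap_reached"`), and the
#'   iteration count `r`.
#' @examples
#' toy <- toy_fixture()
#' ldg <- build_linking_dynamic_graph(toy$network, toy$targets, seed = 1)
#' ldg
#' @export
build_linking_dynamic_graph <- function(network, targets, seed = NULL) {
  with_seed(seed, {
    lev0 <- build_initial_level(network, targets)
    m0 <- kuhn_matching(lev0)
    records <- list(list(level = lev0, matching = m0))
    seen <- chain_key(lev0$right, m0)
    ext <- extend_ldg(network, records, seen,
                      cap = max(1L, length(network$nodes)))
    new_ldg(ext$records, ext$seen, ext$termination, network)
  })
}

#' @export
print.linking_dynamic_graph <- function(x, ...) {
  cat("Linking and dynamic graph:", x$r, "level(s), termination:",
      x$termination, "\n")
  for (rec in x$levels) {
    cat("  B_", rec$level$index, ": |R| = ", length(rec$level$right),
        ", |m| = ", rec$matching$size, "\n", sep = "")
  }
  invisible(x)
}

#' Assemble a linking and dynamic graph from given matchings
#'
#' Builds the level sequence using caller-supplied matchings instead of
#' random maximum matchings, validating at every level that the supplied
#' pairs are links of the level, one-to-one, and of maximum cardinality.
#' Useful for reproducing a documented worked example exactly.
#'
#' @param network a [directed_network()].
#' @param targets target set.
#' @param matchings a list; element \eqn{n} is the matching of level
#'   \eqn{n-1}, given as a list of `c(left, right)` character pairs.
#' @return a `linking_dynamic_graph` (termination `"as_given"`).
#' @export
ldg_from_matchings <- function(network, targets, matchings) {
  lev <- build_initial_level(network, targets)
  records <- list()
  for (k in seq_along(matchings)) {
    pairs <- matchings[[k]]
    pl <- vapply(pairs, `[`, "", 1L)
    pr <- vapply(pairs, `[`, "", 2L)
    li <- node_index(network, pl)
    ri <- node_index(network, pr)
    if (anyDuplicated(li) || anyDuplicated(ri)) {
      stop_usage("matching ", k - 1L, " is not one-to-one")
    }
    pos <- match(ri, lev$right)
    if (anyNA(pos)) stop_usage("matching ", k - 1L,
                               " pairs a node outside the right side")
    ok <- mapply(function(u, p) u %in% lev$adj[[p]], li, pos)
    if (length(ok) && !all(ok)) {
      stop_usage("matching ", k - 1L, " uses a pair that is not a link")
    }
    opt <- with_seed(1L, kuhn_matching(lev))$size
    if (length(li) != opt) {
      stop_usage("matching ", k - 1L, " has size ", length(li),
                 " but the maximum is ", opt)
    }
    n <- length(network$nodes)
    mL <- integer(n); mR <- integer(n)
    mL[li] <- ri; mR[ri] <- li
    m <- structure(list(pairs = cbind(left = mR[sort(ri)], right = sort(ri)),
                        mL = mL, mR = mR, size = length(ri),
                        nodes = network$nodes),
                   class = "matching")
    records[[k]] <- list(level = lev, matching = m)
    right_n <- sort(unique(li))
    lev <- new_level(network, right_n, index = lev$index + 1L)
  }
  seen <- vapply(records, function(r) chain_key(r$level$right, r$matching),
                 "")
  new_ldg(records, seen, "as_given", network)
}

#' Re-match one level avoiding a removed link
#'
#' Deletes one matched link of a level and searches for a replacement
#' maximum matching of the same cardinality that does not use it (via
#' augmenting paths alternating unmatched and matched links).  This is the
#' elementary move of the Markov chain over maximum matchings.
#'
#' @param ldg a `linking_dynamic_graph`.
#' @param level_index the level's index \eqn{n} (0-based, as stored in the
#'   level).
#' @param removed_pair `c(left, right)` character pair, currently matched at
#'   that level.
#' @param seed integer seed or `NULL`.
#' @return a `matching` of unchanged cardinality, or `NULL` if the
#'   cardinality cannot be restored without the removed link.
#' @export
rematch_level <- function(ldg, level_index, removed_pair, seed = NULL) {
  pos <- level_index + 1L
  if (pos < 1L || pos > ldg$r) stop_usage("level index out of range")
  rec <- ldg$levels[[pos]]
  ids <- node_index(structure(list(nodes = ldg$nodes), class = "directed_network"),
                    c(removed_pair[1L], removed_pair[2L]))
  if (rec$matching$mL[ids[1L]] != ids[2L]) {
    stop_usage("pair (", removed_pair[1L], ", ", removed_pair[2L],
               ") is not matched at level ", level_index)
  }
  m <- with_seed(seed, kuhn_matching(rec$level, forbid = ids))
  if (m$size < rec$matching$size) NULL else m
}

#' Matched paths of a linking and dynamic graph
#'
#' Each matched target anchors a path of matched links across levels: the
#' target's matched predecessor at level 0, that node's matched predecessor
#' at level 1, and so on until a node is unmatched.  These paths partition
#' all matched links and are the units the Markov chain proposal picks
#' from.
#'
#' @param ldg a `linking_dynamic_graph`.
#' @return a list of integer matrices with columns `level` (0-based),
#'   `left`, `right` (node indices); one matrix per matched target.
#' @export
matched_paths <- function(ldg) {
  rec0 <- ldg$levels[[1L]]
  paths <- list()
  for (t in rec0$level$right) {
    u <- rec0$matching$mR[t]
    if (u == 0L) next
    rows <- matrix(c(0L, u, t), ncol = 3,
                   dimnames = list(NULL, c("level", "left", "right")))
    cur <- u
    k <- 2L
    while (k <= ldg$r) {
      mk <- ldg$levels[[k]]$matching
      u2 <- mk$mR[cur]
      if (!(cur %in% ldg$levels[[k]]$level$right) || u2 == 0L) break
      rows <- rbind(rows, c(k - 1L, u2, cur))
      cur <- u2
      k <- k + 1L
    }
    paths[[length(paths) + 1L]] <- rows
  }
  paths
}

# ---- exhaustive enumeration (small instances only) --------------------

# All maximum matchings of a level, as a list of integer pair matrices.
# Exponential; intended for worked examples and oracles on tiny levels.
enumerate_level_matchings <- function(level, cap = 10000L) {
  right <- level$right
  adj <- level$adj
  out <- list()
  best <- -1L
  recurse <- function(i, used, pairs) {
    if (length(out) >= cap) return()
    if (i > length(right)) {
      sz <- nrow(pairs)
      if (sz > best) {
        best <<- sz
        out <<- list(pairs)
      } else if (sz == best) {
        out[[length(out) + 1L]] <<- pairs
      }
      return()
    }
    # bound: remaining rights cannot lift size above best + remaining
    if (nrow(pairs) + (length(right) - i + 1L) < best) return()
    for (u in adj[[i]]) {
      if (!used[u]) {
        used[u] <- TRUE
        recurse(i + 1L, used, rbind(pairs, c(u, right[i])))
        used[u] <- FALSE
      }
    }
    recurse(i + 1L, used, pairs)
  }
  recurse(1L, logical(length(level$nodes)),
          matrix(integer(0), ncol = 2, dimnames = list(NULL,
                                                       c("left", "right"))))
  # dedup (identical matchings can be reached along different branches)
  keys <- vapply(out, function(p) {
    o <- order(p[, 2]); paste(p[o, 1], p[o, 2], sep = "-", collapse = ",")
  }, "")
  out[!duplicated(keys)]
}

#' Enumerate all chain states of a small instance
#'
#' Depth-first enumeration of every distinct linking-and-dynamic-graph
#' state: all maximum matchings of level 0, and recursively all maximum
#' matchings of every level they induce.  Exponential in network size;
#' intended as a brute-force oracle on worked examples and small random
#' instances.
#'
#' @param network a [directed_network()].
#' @param targets target set.
#' @param max_states safety cap on the number of states returned.
#' @return a list of `linking_dynamic_graph` objects.
#' @export
enumerate_chain_states <- function(network, targets, max_states = 5000L) {
  lev0 <- build_initial_level(network, targets)
  cap <- max(1L, length(network$nodes))
  states <- list()
  recurse <- function(records, seen) {
    if (length(states) >= max_states) return()
    last <- records[[length(records)]]
    right_n <- sort(unique(last$matching$pairs[, 1L]))
    lev <- if (length(right_n)) {
      new_level(network, right_n, index = last$level$index + 1L)
    }
    if (is.null(lev) || !length(lev$left) || length(records) >= cap) {
      states[[length(states) + 1L]] <<-
        new_ldg(records, seen, "enumerated", network)
      return()
    }
    for (m in enumerate_level_matchings(lev)) {
      n <- length(network$nodes)
      mL <- integer(n); mR <- integer(n)
      mL[m[, 1]] <- m[, 2]; mR[m[, 2]] <- m[, 1]
      mm <- structure(list(pairs = m, mL = mL, mR = mR, size = nrow(m),
                           nodes = network$nodes),
                      class = "matching")
      key <- chain_key(right_n, mm)
      if (key %in% seen) {
        states[[length(states) + 1L]] <<-
          new_ldg(records, seen, "enumerated", network)
      } else {
        recurse(c(records, list(list(level = lev, matching = mm))),
                c(seen, key))
      }
    }
  }
  for (m0 in enumerate_level_matchings(lev0)) {
    n <- length(network$nodes)
    mL <- integer(n); mR <- integer(n)
    mL[m0[, 1]] <- m0[, 2]; mR[m0[, 2]] <- m0[, 1]
    mm <- structure(list(pairs = m0, mL = mL, mR = mR, size = nrow(m0),
                         nodes = network$nodes),
                    class = "matching")
    recurse(list(list(level = lev0, matching = mm)),
            chain_key(lev0$right, mm))
  }
  states
}
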
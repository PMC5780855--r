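# Reference driver-identification schemes used for comparison:
# full-network control via unmatched nodes of one maximum matching, and
# target control via iterated matching that collects unmatched right-side
# nodes.  Neither takes the constraint set into account when selecting
# drivers; the constraint set only enters their reported f2.

new_baseline_result <- function(method, drivers, targets, constraints,
                                extra = list()) {
  fr <- driver_fractions(drivers, targets, constraints)
  structure(c(list(method = method, drivers = sort(as_members(drivers)),
                   f1 = fr$f1, f2 = fr$f2,
                   targets = as_members(targets),
                   constraints = as_members(constraints)),
              extra),
            class = "baseline_result")
}

#' @export
print.baseline_result <- function(x, ...) {
  cat("Baseline (", x$method, "): ", length(x$drivers), " driver(s)\n",
      sep = "")
  cat("  D = {", paste(utils::head(x$drivers, 20), collapse = ", "),
      if (length(x$drivers) > 20) ", ..." else "", "}\n", sep = "")
  cat(sprintf("  f1 = %s  f2 = %s\n",
              if (is.na(x$f1)) "NA" else sprintf("%.4f", x$f1),
              if (is.na(x$f2)) "NA" else sprintf("%.4f", x$f2)))
  invisible(x)
}

#' Full-network control drivers via unmatched nodes
#'
#' The classical minimum-input construction for controlling *every* node:
#' represent the network as one bipartite graph (all nodes as out-copies on
#' the left, all nodes as in-copies on the right, links = edges), compute a
#' maximum matching, and take the unmatched in-copies as driver nodes.  The
#' driver count is always `max(N - |maximum matching|, 1)`: matching
#' cardinality is matching-invariant, and a perfectly matched network still
#' needs one input signal (one arbitrary node is returned in that case).
#'
#' @param network a [directed_network()].
#' @param targets,constraints optional sets used only for the reported
#'   fractions `f1`, `f2`.
#' @param seed integer seed (affects which optimal matching, hence which
#'   unmatched set, is realised - not its size).
#' @return a `baseline_result` with `method = "liu"`, `drivers`, `f1`,
#'   `f2` and `matching_size`.
#' @export
liu_full_control <- function(network, targets = NULL, constraints = NULL,
                             seed = NULL) {
  n <- length(network$nodes)
  lev <- new_level(network, seq_len(n), index = 0L)
  m <- with_seed(seed, kuhn_matching(lev))
  unmatched <- network$nodes[m$mR[seq_len(n)] == 0L]
  if (!length(unmatched)) unmatched <- network$nodes[1L]
  new_baseline_result("liu", unmatched, targets, constraints,
                      extra = list(matching_size = m$size))
}

#' Target-control drivers via iterated matching
#'
#' The iterative unmatched-node construction for controlling a target
#' subset: start with the targets as the right side; at each round compute
#' a maximum matching, add the unmatched right-side nodes to the driver
#' set, and let the matched left nodes become the next right side.  Stops
#' when the right side empties.  When the right side falls into a cyclic
#' repeat (nodes matched around a network cycle, which no upstream node
#' can control without an input), one node of the repeating set is granted
#' driver status and the iteration resumes; drivers are excluded from
#' later right sides.  Because different maximum matchings can leave
#' different nodes unmatched, the driver count can vary with the seed; the
#' smallest driver set over `restarts` seeded restarts is reported.
#'
#' @param network a [directed_network()].
#' @param targets the target set (nonempty).
#' @param constraints optional constraint set, for the reported `f2`.
#' @param seed base seed for the restarts.
#' @param restarts number of seeded restarts (default 10).
#' @return a `baseline_result` with `method = "gao"`.
#' @export
gao_target_control <- function(network, targets, constraints = NULL,
                               seed = 1L, restarts = 10L) {
  o <- as_members(targets)
  t_ids <- node_index(network, o, what = "target")
  if (!length(t_ids)) stop_usage("target set must be nonempty")
  one_run <- function() {
    right <- sort(t_ids)
    drivers <- integer(0)
    seen <- character(0)
    repeat {
      right <- setdiff(right, drivers)  # drivers need no upstream matching
      if (!length(right)) break
      key <- paste(right, collapse = ",")
      if (key %in% seen) {
        # cyclic regress: the residual nodes are matched around network
        # cycles, and a cycle without an input is not controllable; grant
        # one driver to break the cycle and resume the iteration
        drivers <- c(drivers, right[1L])
        seen <- character(0)
        next
      }
      seen <- c(seen, key)
      lev <- new_level(network, right, index = 0L)
      m <- kuhn_matching(lev)
      drivers <- union(drivers, right[m$mR[right] == 0L])
      right <- sort(unique(m$pairs[, 1L]))
    }
    drivers
  }
  best <- NULL
  for (k in seq_len(restarts)) {
    d <- with_seed(seed + k - 1L, one_run())
    if (is.null(best) || length(d) < length(best)) best <- d
  }
  # a controllable system still needs at least one input signal
  if (!length(best)) best <- t_ids[1L]
  new_baseline_result("gao", network$nodes[best], o, constraints)
}

#' Driver-set comparison fractions
#'
#' \eqn{f_1 = |D| / |O|}, the drivers-per-target ratio (cost of control),
#' and \eqn{f_2 = |D \cap Q| / |D|}, the fraction of drivers inside the
#' constraint set (consistency with prior knowledge).  \eqn{f_2} is `NA`
#' when the driver set is empty.
#'
#' @param drivers driver set \eqn{D}.
#' @param targets target set \eqn{O} (nonempty for `f1`).
#' @param constraints constraint set \eqn{Q}.
#' @return a list with numeric `f1` and `f2`.
#' @export
driver_fractions <- function(drivers, targets, constraints = NULL) {
  d <- as_members(drivers)
  o <- as_members(targets)
  q <- as_members(constraints)
  list(f1 = if (length(o)) length(d) / length(o) else NA_real_,
       f2 = if (length(d)) length(intersect(d, q)) / length(d)
            else NA_real_)
}
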
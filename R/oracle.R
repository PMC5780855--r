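# Numeric verification of structural target controllability.
#
# A driver set D renders the target set O structurally controllable when,
# for a generic choice of nonzero weights on the network's adjacency
# support, the output controllability matrix
#   K = [CB, CAB, CA^2 B, ..., CA^{N-1} B]
# has rank |O|, where A carries the edge weights (edge u -> v gives a
# nonzero at row v, column u, matching dx/dt = A x), B's columns are
# indicator vectors of the drivers and C's rows are indicators of the
# targets.  Genericity is approximated by taking the maximum rank over a
# few independent random weight draws; A is rescaled to spectral radius
# < 1 before powering so that the N-1 powers neither overflow nor
# underflow (rank is invariant to this rescaling).

#' Generic rank condition for target controllability
#'
#' @param network a [directed_network()].
#' @param drivers driver set \eqn{D} (character vector; may be empty).
#' @param targets target set \eqn{O} (nonempty).
#' @param trials independent random-weight draws (default 3); the generic
#'   rank is the maximum over draws.
#' @param weight_range magnitude interval for the random weights, excluding
#'   zero (default \[0.5, 1.5\], with random sign).
#' @param tol relative singular-value threshold for the numeric rank
#'   (default 1e-8).
#' @param rescale rescale \eqn{A} to spectral radius < 1 before powering
#'   (default `TRUE`).
#' @param n_cap refuse networks larger than this (default 500): the dense
#'   block build is meant for verification-scale instances, not
#'   interactome-scale ones.
#' @param seed integer seed or `NULL`.
#' @return logical: does some draw achieve rank \eqn{|O|}?
#' @examples
#' toy <- toy_fixture()
#' generic_target_rank(toy$network, "v1", toy$targets, seed = 1)
#' @export
generic_target_rank <- function(network, drivers, targets, trials = 3L,
                                weight_range = c(0.5, 1.5), tol = 1e-8,
                                rescale = TRUE, n_cap = 500L, seed = NULL) {
  out <- target_rank_value(network, drivers, targets, trials = trials,
                           weight_range = weight_range, tol = tol,
                           rescale = rescale, n_cap = n_cap, seed = seed)
  out$rank >= out$no
}

# internal core: best numeric rank over trials, plus the required rank |O|
target_rank_value <- function(network, drivers, targets, trials = 3L,
                              weight_range = c(0.5, 1.5), tol = 1e-8,
                              rescale = TRUE, n_cap = 500L, seed = NULL) {
  n <- length(network$nodes)
  if (n > n_cap) {
    stop_usage("network has ", n, " nodes, above the dense-rank cap of ",
               n_cap, "; use a Krylov/iterative block build for networks ",
               "this large")
  }
  o_ids <- node_index(network, as_members(targets), what = "target")
  d_ids <- node_index(network, as_members(drivers), what = "driver")
  no <- length(o_ids)
  if (!no) stop_usage("target set must be nonempty")
  if (!length(d_ids)) return(list(rank = 0L, no = no))
  edges <- network$edges
  rank_best <- with_seed(seed, {
    best <- 0L
    for (trial in seq_len(trials)) {
      a <- matrix(0, n, n)
      w <- stats::runif(nrow(edges), weight_range[1], weight_range[2]) *
        sample(c(-1, 1), nrow(edges), replace = TRUE)
      a[cbind(edges[, "to"], edges[, "from"])] <- w
      if (rescale && nrow(edges)) {
        rho <- max(Mod(eigen(a, only.values = TRUE)$values))
        if (rho > 0) a <- a / (1.1 * rho)
      }
      x <- diag(1, n)[, d_ids, drop = FALSE]  # B
      k_blocks <- matrix(0, no, 0)
      rank_now <- 0L
      for (p in seq_len(n)) {
        k_blocks <- cbind(k_blocks, x[o_ids, , drop = FALSE])  # C A^{p-1} B
        sv <- svd(k_blocks, nu = 0, nv = 0)$d
        rank_now <- sum(sv > tol * max(sv, 0) & sv > 0)
        if (rank_now >= no) break
        if (p < n) x <- a %*% x
      }
      best <- max(best, rank_now)
      if (best >= no) break
    }
    best
  })
  list(rank = rank_best, no = no)
}

#' Verify a driver selection end to end
#'
#' Runs the generic rank condition for the selection and, when a
#' controllable-subspace map is supplied, additionally checks the covering
#' property \eqn{\bigcup_{d \in D} TCS(d) \supseteq O}.
#'
#' @param network a [directed_network()].
#' @param selection a `driver_selection`, fitted `tcoa` object, or a
#'   character vector of drivers.
#' @param targets target set \eqn{O}.
#' @param tcs optional `tcs_map` for the covering check.
#' @param ... passed to [generic_target_rank()].
#' @return a list with logicals `rank_ok`, `coverage_ok` (`NA` when no
#'   `tcs` given), `pass`, and the `drivers` checked.
#' @export
verify_selection <- function(network, selection, targets, tcs = NULL, ...) {
  drivers <- if (inherits(selection, "driver_selection") ||
                 inherits(selection, "tcoa")) {
    selection$drivers
  } else {
    as_members(selection)
  }
  o <- as_members(targets)
  rank_ok <- generic_target_rank(network, drivers, o, ...)
  coverage_ok <- NA
  if (!is.null(tcs)) {
    covered <- unique(unlist(tcs$tcs[drivers]))
    coverage_ok <- all(o %in% covered)
  }
  list(drivers = drivers, rank_ok = rank_ok, coverage_ok = coverage_ok,
       pass = rank_ok && !isFALSE(coverage_ok))
}
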
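# Controllability surfaces over target/constraint fractions, and topology
# statistics of driver sets.
#
# Two scalar efficiency measures summarise a method on a network: E1, the
# grid-mean of ||D(alpha, beta)|| / ||O(alpha)|| (cost of control), and
# E2, the grid-mean of ||D(alpha, beta) n Q|| / ||D(alpha, beta)||
# (consistency of the drivers with the pre-selected set), where O and Q
# are uniform random node samples of fractions alpha and beta.  The double
# integrals over (alpha, beta) in (0, 1]^2 are discretised as unweighted
# means over the evaluation grid.

#' Sample target and constraint sets of given fractions
#'
#' \eqn{O} is a uniform sample without replacement of `round(alpha * N)`
#' nodes; \eqn{Q} likewise of `round(beta * N)` nodes, sampled
#' independently (the sets may overlap).
#'
#' @param network a [directed_network()].
#' @param alpha,beta fractions in (0, 1]; a fraction that rounds to zero
#'   nodes is an error.
#' @param seed integer seed or `NULL` for the current RNG stream.
#' @return a list with `targets` and `constraints` ([node_subset()]s).
#' @export
sample_target_constraint_sets <- function(network, alpha, beta,
                                          seed = NULL) {
  n <- length(network$nodes)
  if (alpha <= 0 || alpha > 1 || beta <= 0 || beta > 1) {
    stop_usage("alpha and beta must lie in (0, 1]")
  }
  n_o <- round(alpha * n)
  n_q <- round(beta * n)
  if (n_o < 1 || n_q < 1) {
    stop_usage("fraction rounds to zero nodes on a network of size ", n)
  }
  with_seed(seed, {
    o <- sample_vec(network$nodes, n_o)
    q <- sample_vec(network$nodes, n_q)
    list(targets = node_subset(o, network, role = "target"),
         constraints = node_subset(q, network, role = "constraint"))
  })
}

#' Controllability surface over an (alpha, beta) grid
#'
#' For every grid cell, draws `repeats` independent (O, Q) pairs of the
#' given fractions, runs the chosen driver-identification method, and
#' averages the two ratios \eqn{|D|/|O|} and \eqn{|D \cap Q|/|D|}.  The
#' scalars `E1` and `E2` are the unweighted grid means.
#'
#' @param network a [directed_network()].
#' @param method `"tcoa"` or `"gao"` (the latter ignores \eqn{Q} when
#'   selecting drivers, so its E2 reflects chance overlap).
#' @param alpha,beta grid values (defaults `seq(0.1, 1, 0.1)`).
#' @param repeats independent (O, Q) draws per cell (default 10).
#' @param seed integer seed for the whole surface.
#' @param control list of sampler settings forwarded to [tcoa()]
#'   (`c`, `max_iter`, `window`, `burn_in`); ignored for `"gao"`.
#' @param restarts restarts for [gao_target_control()].
#' @return an object of class `controllability_surface`: `grid` (data
#'   frame `alpha`, `beta`, `ratio_drivers`, `ratio_constrained`), scalars
#'   `E1`, `E2`, and the `method`.
#' @export
controllability_surface <- function(network, method = c("tcoa", "gao"),
                                    alpha = seq(0.1, 1, 0.1),
                                    beta = seq(0.1, 1, 0.1),
                                    repeats = 10L, seed = 1L,
                                    control = list(), restarts = 3L) {
  method <- match.arg(method)
  if (!length(alpha) || !length(beta)) stop_usage("grid must be nonempty")
  ctl <- utils::modifyList(list(c = 10, max_iter = 200L, window = 50L,
                                burn_in = 0L), control)
  grid <- expand.grid(alpha = alpha, beta = beta)
  r1 <- r2 <- numeric(nrow(grid))
  with_seed(seed, {
    for (i in seq_len(nrow(grid))) {
      v1 <- v2 <- numeric(0)
      for (rep in seq_len(repeats)) {
        sets <- sample_target_constraint_sets(network, grid$alpha[i],
                                              grid$beta[i])
        d <- if (method == "tcoa") {
          sub_seed <- sample.int(2^30, 1L)
          fit <- tcoa(network, sets$targets, sets$constraints,
                      c = ctl$c, max_iter = ctl$max_iter,
                      window = ctl$window, burn_in = ctl$burn_in,
                      seed = sub_seed)
          if (!fit$feasible) next
          fit$drivers
        } else {
          sub_seed <- sample.int(2^30, 1L)
          gao_target_control(network, sets$targets, sets$constraints,
                             seed = sub_seed, restarts = restarts)$drivers
        }
        fr <- driver_fractions(d, sets$targets, sets$constraints)
        v1 <- c(v1, fr$f1)
        v2 <- c(v2, fr$f2)
      }
      r1[i] <- mean(v1)
      r2[i] <- mean(v2, na.rm = TRUE)
    }
  })
  grid$ratio_drivers <- r1
  grid$ratio_constrained <- r2
  structure(list(grid = grid, E1 = mean(r1, na.rm = TRUE),
                 E2 = mean(r2, na.rm = TRUE), method = method,
                 repeats = repeats, seed = seed),
            class = "controllability_surface")
}

#' @export
print.controllability_surface <- function(x, ...) {
  cat("Controllability surface (", x$method, "): ",
      nrow(x$grid), " cells x ", x$repeats, " repeats\n", sep = "")
  cat(sprintf("  E1 = %.4f  E2 = %.4f\n", x$E1, x$E2))
  invisible(x)
}

#' Topology statistics of a node set
#'
#' Mean out-degree and mean directed betweenness centrality
#' (unnormalised) of a node set, alongside the whole-network means, for
#' asking whether driver nodes sit on hubs and bridges.
#'
#' @param network a [directed_network()].
#' @param node_set nonempty character vector of nodes.
#' @return a list with `set_out_degree`, `set_betweenness`,
#'   `network_out_degree`, `network_betweenness`, and the set `size`.
#' @export
topology_stats <- function(network, node_set) {
  members <- as_members(node_set)
  if (!length(members)) stop_usage("node_set must be nonempty")
  node_index(network, members)
  g <- as_igraph(network)
  outdeg <- igraph::degree(g, mode = "out")
  btw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  list(set_out_degree = mean(outdeg[members]),
       set_betweenness = mean(btw[members]),
       network_out_degree = mean(outdeg),
       network_betweenness = mean(btw),
       size = length(members))
}
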
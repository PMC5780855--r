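# Metropolis-Hastings sampling over maximum matchings.
#
# A chain state is one realisation of the linking and dynamic graph
# together with everything it induces: target control tree, controllable
# subspaces, and the ILP-optimal driver selection with weight W.  The
# proposal deletes one matched link from a uniformly chosen matched path,
# re-matches that level without it, and rebuilds all deeper levels; levels
# above the touched one are untouched.
#
# Acceptance uses probability min[1, exp(-c * (W_new - W_old))], i.e. the
# stationary weight is proportional to exp(-c * W): improvements (lower W)
# are always accepted and worsening moves are exponentially damped.  Note
# the sign: a sampler favouring *high* W would contradict the minimisation
# objective the ILP step optimises, so low-W states are the ones favoured
# here (see the methods vignette for discussion of this choice).

build_chain_state <- function(network, targets, constraints, ldg) {
  tct <- build_target_control_tree(ldg)
  tcs <- controllable_subspace_map(tct, network, targets)
  sel <- solve_driver_ilp(tcs$families, targets, constraints)
  list(ldg = ldg, tct = tct, tcs = tcs, selection = sel, W = sel$W)
}

#' Metropolis acceptance probability for a weight change
#'
#' \eqn{p = \min[1, \exp(-c (W_{new} - W_{old}))]}: moves to lower weight
#' are always accepted; a weight increase of \eqn{\Delta W} is accepted
#' with probability \eqn{e^{-c\Delta W}}.
#'
#' @param w_old,w_new weights of the current and proposed states.
#' @param c positive temperature-like constant (default 10).
#' @return the acceptance probability, in \[0, 1\].
#' @examples
#' metropolis_probability(2, 3, c = 10)  # exp(-10)
#' @export
metropolis_probability <- function(w_old, w_new, c = 10) {
  if (c <= 0) stop_usage("c must be positive")
  min(1, exp(-c * (w_new - w_old)))
}

#' Metropolis accept/reject draw
#'
#' @inheritParams metropolis_probability
#' @return logical: accept the proposed state?
#' @export
metropolis_accept <- function(w_old, w_new, c = 10) {
  stats::runif(1) < metropolis_probability(w_old, w_new, c)
}

#' Propose a neighbouring chain state
#'
#' Picks a matched path uniformly at random, then a matched link within it;
#' deletes that link, re-matches its level ([rematch_level()] semantics)
#' and rebuilds all deeper levels with fresh matchings.  Levels above the
#' touched one are carried over unchanged.  If the level's matching
#' cardinality cannot be restored without the deleted link, the proposal
#' fails (`NULL`), which the sampler treats as a rejection.
#'
#' @param state a chain state as built internally by [tcoa()] (list with
#'   `ldg`, `tct`, `tcs`, `selection`, `W`).
#' @param network,targets,constraints the problem instance.
#' @return a new chain state, or `NULL` if the proposal failed.
#' @keywords internal
propose_rewire <- function(state, network, targets, constraints) {
  paths <- matched_paths(state$ldg)
  if (!length(paths)) return(NULL)
  path <- paths[[sample.int(length(paths), 1L)]]
  row <- path[sample.int(nrow(path), 1L), ]
  k0 <- row[["level"]]
  pos <- k0 + 1L
  rec <- state$ldg$levels[[pos]]
  newm <- kuhn_matching(rec$level, forbid = c(row[["left"]], row[["right"]]))
  if (newm$size < rec$matching$size) return(NULL)
  records <- state$ldg$levels[seq_len(pos - 1L)]
  records[[pos]] <- list(level = rec$level, matching = newm)
  seen <- vapply(records, function(r) chain_key(r$level$right, r$matching),
                 "")
  ext <- extend_ldg(network, records, seen,
                    cap = max(1L, length(network$nodes)))
  ldg <- new_ldg(ext$records, ext$seen, ext$termination, network)
  out <- build_chain_state(network, targets, constraints, ldg)
  out$rewired_level <- k0
  out
}

# Core sampling loop; called by tcoa() with the RNG already seeded.
run_sampler <- function(network, targets, constraints, c, max_iter, window,
                        burn_in) {
  ldg0 <- build_linking_dynamic_graph(network, targets)
  state <- build_chain_state(network, targets, constraints, ldg0)
  if (!state$selection$feasible) {
    return(list(feasible = FALSE, selection = state$selection))
  }
  best <- state$selection
  since_improve <- 0L
  it <- 0L
  w_cur <- integer(max_iter)
  w_best <- integer(max_iter)
  accepted <- logical(max_iter)
  driver_sets <- vector("list", max_iter)
  while (it < max_iter) {
    it <- it + 1L
    prop <- propose_rewire(state, network, targets, constraints)
    acc <- FALSE
    if (!is.null(prop) && prop$selection$feasible &&
        metropolis_accept(state$W, prop$W, c)) {
      state <- prop
      acc <- TRUE
    }
    if (state$W < best$W) {
      best <- state$selection
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    w_cur[it] <- state$W
    w_best[it] <- best$W
    accepted[it] <- acc
    driver_sets[[it]] <- state$selection$drivers
    if (since_improve >= window) break
  }
  list(feasible = TRUE, selection = best, final_state = state,
       trace = data.frame(iteration = seq_len(it),
                          W = w_cur[seq_len(it)],
                          W_best = w_best[seq_len(it)],
                          accepted = accepted[seq_len(it)]),
       driver_sets = driver_sets[seq_len(it)],
       converged = since_improve >= window,
       iterations = it,
       burn_in = burn_in)
}

# Post-sampling verification against the generic rank condition.
#
# The tree-reachability construction is an approximation: on cyclic
# networks a node can be credited with two targets that share a single
# parent at equal delay, which no input through that junction can steer
# independently.  The selections the sampler visited are therefore
# screened (in order of weight) with the rank oracle, and if none
# certifies, the best selection is repaired by granting direct inputs on
# targets until the rank condition holds (a driver on every target always
# does, so the loop terminates).  `max_screen` bounds the number of
# distinct selections screened.
verify_and_repair <- function(network, res, targets, constraints, seed,
                              max_screen = 20L) {
  sets <- c(list(res$selection$drivers), res$driver_sets)
  ws <- c(res$selection$W, res$trace$W)
  first <- !duplicated(vapply(sets, paste, "", collapse = ","))
  cands <- sets[first]
  ord <- order(ws[first])
  cands <- cands[ord][seq_len(min(length(cands), max_screen))]
  for (d in cands) {
    if (generic_target_rank(network, d, targets, seed = seed)) {
      return(list(drivers = d, repaired = FALSE, verified = TRUE))
    }
  }
  # repair: add direct inputs, constrained nodes first, until full rank
  d <- res$selection$drivers
  pool <- c(intersect(targets, constraints),
            setdiff(targets, constraints))
  pool <- setdiff(pool, d)
  rk <- target_rank_value(network, d, targets, seed = seed)
  for (u in pool) {
    if (rk$rank >= rk$no) break
    rk2 <- target_rank_value(network, c(d, u), targets, seed = seed)
    if (rk2$rank > rk$rank) {
      d <- c(d, u)
      rk <- rk2
    }
  }
  list(drivers = d, repaired = TRUE, verified = rk$rank >= rk$no)
}

#' Per-node control capacity from sampled driver sets
#'
#' The control capacity \eqn{f_d(v)} of a node is the fraction of retained
#' sampled driver sets that contain it.  By default every retained
#' (post-burn-in) state of the chain counts, including repeats after
#' rejected proposals; with `optima_only = TRUE` only states attaining the
#' best weight seen are counted.
#'
#' @param x a fitted [tcoa()] object, or a list of character driver sets.
#' @param optima_only count only best-weight states (only meaningful for a
#'   fitted object, where the best weight is known).
#' @return a data frame with columns `node` and `fd`, sorted by decreasing
#'   capacity; attribute `samples` holds the retained sample count.
#' @export
control_capacity <- function(x, optima_only = FALSE) {
  if (inherits(x, "tcoa")) {
    sets <- x$driver_sets
    keep <- seq_along(sets) > x$config$burn_in
    if (optima_only) keep <- keep & (x$trace$W == x$W)
    sets <- sets[keep]
  } else {
    sets <- x
  }
  if (!length(sets)) stop_usage("no retained samples to count")
  counts <- table(unlist(sets))
  fd <- as.numeric(counts) / length(sets)
  out <- data.frame(node = names(counts), fd = fd,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$fd, out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "samples") <- length(sets)
  out
}
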
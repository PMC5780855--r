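# Objectives-guided driver selection.
#
# The scalarised objective is W(M) = ||D|| + ||D - Q|| = 2*||D|| - ||D n Q||:
# a driver inside the constraint set Q costs 1, any other driver costs 2.
# Minimising W subject to "every target u is covered by some driver in its
# family F_u" is a weighted set-cover integer program (the y indicators of
# the two-objective formulation are bound to x on Q, which is exactly this
# cost reformulation).  It is solved exactly by branch and bound with
# component decomposition, dominance reduction and an admissible
# disjoint-target lower bound; a brute-force subset-enumeration oracle is
# provided for verification on small instances.

#' Weight and outlier count of a driver set
#'
#' \eqn{W = 2|D| - |D \cap Q| = |D| + |D \setminus Q|} and
#' \eqn{\mu = |D \setminus Q|}, the number of drivers outside the
#' pre-selected set.  Pure arithmetic on deduplicated sets.
#'
#' @param drivers driver set \eqn{D} (character vector or [node_subset()]).
#' @param constraints constraint set \eqn{Q}.
#' @return a list with integer elements `W` and `mu`.
#' @examples
#' driver_weight(c("v3"), "v1")  # W = 2: one driver, outside Q
#' driver_weight(c("v1"), "v1")  # W = 1: one driver, inside Q
#' @export
driver_weight <- function(drivers, constraints) {
  d <- as_members(drivers)
  q <- as_members(constraints)
  list(W = 2L * length(d) - length(intersect(d, q)),
       mu = length(setdiff(d, q)))
}

new_driver_selection <- function(drivers, constraints, feasible,
                                 uncoverable = character(0)) {
  wt <- driver_weight(drivers, constraints)
  structure(list(drivers = sort(as_members(drivers)), W = wt$W, mu = wt$mu,
                 feasible = feasible, uncoverable = uncoverable),
            class = "driver_selection")
}

#' @export
print.driver_selection <- function(x, ...) {
  if (!x$feasible) {
    cat("Driver selection: infeasible; uncoverable target(s):",
        paste(x$uncoverable, collapse = ", "), "\n")
  } else {
    cat("Driver selection: D = {", paste(x$drivers, collapse = ", "),
        "}, W =", x$W, ", mu =", x$mu, "\n")
  }
  invisible(x)
}

# ---- branch and bound -------------------------------------------------

# families: list of integer candidate vectors per target (indices into
# cand universe); cost: per-candidate cost.  Returns indices of an optimal
# cover and its cost.  Exact.
bb_set_cover <- function(fam, cost) {
  tn <- length(fam)
  if (!tn) return(list(chosen = integer(0), cost = 0))
  # candidate -> targets it covers
  k <- length(cost)
  cover <- vector("list", k)
  for (u in seq_len(tn)) {
    for (v in fam[[u]]) cover[[v]] <- c(cover[[v]], u)
  }
  # dominance among candidates: v is dropped if some kept v' has
  # cover(v) subset cover(v') and cost(v') <= cost(v) (first-kept wins ties)
  ord <- order(cost, -lengths(cover))
  kept <- logical(k)
  for (v in ord) {
    if (!length(cover[[v]])) next
    dominated <- FALSE
    for (w in which(kept)) {
      if (cost[w] <= cost[v] && all(cover[[v]] %in% cover[[w]])) {
        dominated <- TRUE
        break
      }
    }
    kept[v] <- !dominated
  }
  fam <- lapply(fam, function(f) f[kept[f]])
  if (any(lengths(fam) == 0)) return(NULL)  # guarded by caller
  # dominance among targets: if F_u' is a subset of F_u, any cover of u'
  # covers u too, so u can be dropped (first-kept wins for duplicates)
  t_ord <- order(lengths(fam))
  kept_t <- integer(0)
  for (j in t_ord) {
    dom <- FALSE
    for (i in kept_t) {
      if (all(fam[[i]] %in% fam[[j]])) {
        dom <- TRUE
        break
      }
    }
    if (!dom) kept_t <- c(kept_t, j)
  }
  fam <- fam[kept_t]
  tn <- length(fam)
  cheapest <- vapply(fam, function(f) min(cost[f]), 0)
  # greedy incumbent (upper bound): max new coverage per unit cost
  greedy <- function() {
    uncovered <- rep(TRUE, tn)
    chosen <- integer(0)
    while (any(uncovered)) {
      live <- which(uncovered)
      gain <- vapply(seq_along(cover), function(v) {
        if (!kept[v]) return(0)
        sum(vapply(live, function(u) v %in% fam[[u]], FALSE)) / cost[v]
      }, 0)
      v <- which.max(gain)
      if (gain[v] == 0) break
      chosen <- c(chosen, v)
      uncovered[live[vapply(live, function(u) v %in% fam[[u]], FALSE)]] <- FALSE
    }
    chosen
  }
  inc <- greedy()
  best <- list(chosen = inc, cost = sum(cost[inc]))
  # admissible lower bound: a maximal family-disjoint target set; each
  # selected target needs its own candidate, so their cheapest costs add
  lower_bound <- function(uncovered) {
    lb <- 0
    live <- which(uncovered)
    while (length(live)) {
      i <- live[which.min(cheapest[live])]
      lb <- lb + cheapest[i]
      touched <- fam[[i]]
      live <- live[!vapply(live, function(u) any(fam[[u]] %in% touched),
                           FALSE)]
    }
    lb
  }
  dfs <- function(uncovered, chosen, acc) {
    if (!any(uncovered)) {
      if (acc < best$cost) best <<- list(chosen = chosen, cost = acc)
      return()
    }
    if (acc + lower_bound(uncovered) >= best$cost) return()
    live <- which(uncovered)
    u <- live[which.min(lengths(fam[live]))]
    cands <- fam[[u]]
    cands <- cands[order(cost[cands],
                         -vapply(cands, function(v) length(cover[[v]]), 0L),
                         cands)]
    for (v in cands) {
      unc2 <- uncovered
      for (i in which(uncovered)) if (v %in% fam[[i]]) unc2[i] <- FALSE
      dfs(unc2, c(chosen, v), acc + cost[v])
    }
  }
  dfs(rep(TRUE, tn), integer(0), 0)
  best
}

#' Select an optimal driver set by integer programming
#'
#' Minimises \eqn{W = 2|D| - |D \cap Q|} subject to every target being
#' covered by at least one driver from its family \eqn{F_u}, solved exactly
#' as a weighted set cover (cost 1 for candidates in \eqn{Q}, 2 otherwise)
#' by LP-free branch and bound with component decomposition.  Targets with
#' an empty family make the instance infeasible; they are reported in the
#' result, not raised as an error.
#'
#' @param families named list: per-target character vectors of candidate
#'   drivers (e.g. `covering_families()$families`), or a `tcs_map`.
#' @param targets the target set (defaults to `names(families)`).
#' @param constraints the constraint set \eqn{Q}.
#' @return a `driver_selection`: `drivers`, `W`, `mu`, `feasible`,
#'   `uncoverable`.
#' @export
solve_driver_ilp <- function(families, targets = NULL, constraints = NULL) {
  if (inherits(families, "tcs_map")) families <- families$families
  targets <- as_members(targets %||% names(families))
  q <- as_members(constraints)
  fam <- families[targets]
  names(fam) <- targets
  empty <- targets[vapply(fam, function(f) length(as_members(f)) == 0, TRUE)]
  if (length(empty)) {
    return(new_driver_selection(character(0), q, feasible = FALSE,
                                uncoverable = empty))
  }
  cand <- sort(unique(unlist(fam)))
  cost <- ifelse(cand %in% q, 1, 2)
  fam_i <- lapply(fam, function(f) match(as_members(f), cand))
  # connected components over "targets sharing a candidate"
  comp <- seq_along(targets)
  repeat {
    changed <- FALSE
    for (v in seq_along(cand)) {
      touch <- which(vapply(fam_i, function(f) v %in% f, FALSE))
      if (length(touch) > 1) {
        m <- min(comp[touch])
        if (any(comp[touch] != m)) {
          comp[touch] <- m
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  chosen <- integer(0)
  for (cc in unique(comp)) {
    sel <- bb_set_cover(fam_i[comp == cc], cost)
    chosen <- c(chosen, sel$chosen)
  }
  new_driver_selection(cand[unique(chosen)], q, feasible = TRUE)
}

#' Brute-force minimum-weight driver set
#'
#' Exhaustive enumeration over all subsets of the candidate universe; the
#' independent optimum oracle for [solve_driver_ilp()].  Capped (default 20
#' candidates) because the search is exponential.
#'
#' @param families named list of per-target candidate vectors, or a
#'   `tcs_map`.
#' @param constraints the constraint set \eqn{Q}.
#' @param cap maximum candidate count.
#' @return a list with `W` (global minimum weight), `drivers` (one argmin),
#'   and `feasible`.
#' @export
brute_force_min_weight <- function(families, constraints = NULL, cap = 20L) {
  if (inherits(families, "tcs_map")) families <- families$families
  q <- as_members(constraints)
  fam <- lapply(families, as_members)
  if (any(lengths(fam) == 0)) {
    return(list(W = NA_integer_, drivers = character(0), feasible = FALSE))
  }
  cand <- sort(unique(unlist(fam)))
  k <- length(cand)
  if (k > cap) stop_usage("candidate count ", k, " exceeds cap ", cap)
  cost <- ifelse(cand %in% q, 1L, 2L)
  # bitmask coverage per candidate over targets (<= 30 targets per word)
  tn <- length(fam)
  if (tn > 30L) stop_usage("too many targets for the bitmask oracle")
  cmask <- vapply(cand, function(v) {
    sum(bitwShiftL(1L, which(vapply(fam, function(f) v %in% f, FALSE)) - 1L))
  }, 0L)
  full <- if (tn) sum(bitwShiftL(1L, seq_len(tn) - 1L)) else 0L
  best_w <- Inf
  best_set <- integer(0)
  for (s in 0:(2^k - 1)) {
    members <- which(bitwAnd(bitwShiftR(s, seq_len(k) - 1L), 1L) == 1L)
    covered <- 0L
    for (v in members) covered <- bitwOr(covered, cmask[v])
    if (covered == full) {
      w <- sum(cost[members])
      if (w < best_w) {
        best_w <- w
        best_set <- members
      }
    }
  }
  list(W = as.integer(best_w), drivers = cand[best_set], feasible = TRUE)
}
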
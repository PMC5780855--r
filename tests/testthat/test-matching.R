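toy <- toy_fixture()

test_that("the initial bipartite level is the direct-predecessor graph", {
  lev <- build_initial_level(toy$network, toy$targets)
  expect_setequal(toy$network$nodes[lev$right], c("v3", "v4", "v6"))
  expect_setequal(toy$network$nodes[lev$left],
                  c("v1", "v2", "v3", "v4", "v5"))
  # edges into targets: v1,v2,v4 -> v3; v3 -> v4; v5 -> v6
  links <- level_links(lev)
  expect_equal(nrow(links), 5)
  expect_setequal(paste(links[, 1], links[, 2]),
                  c("v1 v3", "v2 v3", "v4 v3", "v3 v4", "v5 v6"))

  # a target with no in-edges appears on the right but attracts no links
  net <- directed_network(cbind("a", "b"), nodes = c("a", "b", "c"))
  lev2 <- build_initial_level(net, c("b", "c"))
  expect_setequal(net$nodes[lev2$right], c("b", "c"))
  expect_setequal(net$nodes[lev2$left], "a")

  # self-loop: the node is its own predecessor
  loop <- directed_network(cbind("a", "a"))
  lev3 <- build_initial_level(loop, "a")
  expect_equal(loop$nodes[lev3$left], "a")
  expect_equal(nrow(level_links(lev3)), 1)

  expect_error(build_initial_level(toy$network, character(0)),
               class = "tcoa_usage_error")
})

test_that("matching cardinality is maximum and seed-invariant", {
  lev <- build_initial_level(toy$network, toy$targets)
  sizes <- vapply(1:10, function(s) maximum_matching(lev, seed = s)$size,
                  0L)
  expect_true(all(sizes == 3L))
  # the documented matching {(v2,v3),(v3,v4),(v5,v6)} is one valid outcome
  found <- FALSE
  for (s in 1:50) {
    p <- matching_pairs(maximum_matching(lev, seed = s))
    if (setequal(paste(p[, 1], p[, 2]), c("v2 v3", "v3 v4", "v5 v6"))) {
      found <- TRUE
      break
    }
  }
  expect_true(found)

  # level with no links -> empty matching
  net <- directed_network(nodes = c("a", "b"))
  expect_equal(maximum_matching(build_initial_level(net, "a"))$size, 0L)
})

test_that("matching size equals brute force on random bipartite levels", {
  for (s in 1:200) {
    inst <- random_instance(s, n_max = 10L)
    o <- inst$targets
    lev <- build_initial_level(inst$network, o)
    got <- maximum_matching(lev, seed = s)$size
    want <- bf_matching_size(bf_level_adj(inst$network, o))
    expect_equal(got, want, info = paste("seed", s))
  }
})

test_that("the level chain invariant R_n = matched(m_{n-1}) holds", {
  for (s in 1:25) {
    inst <- random_instance(s)
    ldg <- build_linking_dynamic_graph(inst$network, inst$targets,
                                       seed = s)
    for (k in seq_len(ldg$r)[-1]) {
      prev <- ldg$levels[[k - 1]]$matching
      expect_equal(sort(ldg$levels[[k]]$level$right),
                   sort(unique(prev$pairs[, "left"])))
      # stored matchings are maximum for their level (oracle check)
      right_names <- inst$network$nodes[ldg$levels[[k]]$level$right]
      expect_equal(ldg$levels[[k]]$matching$size,
                   bf_matching_size(bf_level_adj(inst$network,
                                                 right_names)))
    }
  }
})

test_that("iteration terminates on cycles and on source-only targets", {
  cyc <- directed_network(rbind(c("a", "b"), c("b", "a")))
  ldg <- build_linking_dynamic_graph(cyc, "a", seed = 1)
  expect_true(ldg$termination %in% c("repeat_detected", "cap_reached"))
  expect_lte(ldg$r, 2)

  # targets that are pure sources: single level, empty matching
  net <- directed_network(cbind("x", "y"), nodes = c("x", "y", "z"))
  ldg2 <- build_linking_dynamic_graph(net, c("x", "z"), seed = 1)
  expect_equal(ldg2$r, 1)
  expect_equal(ldg2$levels[[1]]$matching$size, 0L)
  expect_equal(ldg2$termination, "empty_left")
})

test_that("rematching a level restores cardinality without the removed link", {
  ldg <- ldg_from_matchings(toy$network, toy$targets,
                            toy_printed_matchings())
  for (s in 1:10) {
    m <- rematch_level(ldg, 0L, c("v2", "v3"), seed = s)
    expect_false(is.null(m))
    expect_equal(m$size, 3L)
    p <- matching_pairs(m)
    expect_false("v2 v3" %in% paste(p[, 1], p[, 2]))
    # replacement predecessor of v3 must be v1 or v4
    expect_true(p[p[, 2] == "v3", 1] %in% c("v1", "v4"))
  }
  # a right node with a single predecessor cannot be rematched
  chain <- directed_network(cbind("a", "b"))
  ldg2 <- build_linking_dynamic_graph(chain, "b", seed = 1)
  expect_null(rematch_level(ldg2, 0L, c("a", "b"), seed = 1))
  # usage errors
  expect_error(rematch_level(ldg, 5L, c("v2", "v3")),
               class = "tcoa_usage_error")
  expect_error(rematch_level(ldg, 0L, c("v1", "v3")),
               class = "tcoa_usage_error")
})

test_that("supplied matchings are validated before being adopted", {
  bad_pair <- list(list(c("v5", "v3")))  # not a link of B_0
  expect_error(ldg_from_matchings(toy$network, toy$targets, bad_pair),
               class = "tcoa_usage_error")
  not_max <- list(list(c("v2", "v3")))   # size 1 < maximum 3
  expect_error(ldg_from_matchings(toy$network, toy$targets, not_max),
               class = "tcoa_usage_error")
  not_injective <- list(list(c("v2", "v3"), c("v2", "v4"),
                             c("v5", "v6")))
  expect_error(ldg_from_matchings(toy$network, toy$targets, not_injective),
               class = "tcoa_usage_error")
})

test_that("matched paths partition the matched links and anchor at targets", {
  for (s in 1:10) {
    ldg <- build_linking_dynamic_graph(toy$network, toy$targets, seed = s)
    paths <- matched_paths(ldg)
    # every matched link appears in exactly one path
    all_rows <- do.call(rbind, paths)
    key <- paste(all_rows[, "level"], all_rows[, "left"],
                 all_rows[, "right"])
    expect_equal(anyDuplicated(key), 0L)
    n_links <- sum(vapply(ldg$levels, function(r) r$matching$size, 0L))
    expect_equal(nrow(all_rows), n_links)
    # each path starts at a matched target
    starts <- vapply(paths, function(p) p[1, "right"], 0L)
    expect_true(all(starts %in% ldg$levels[[1]]$level$right))
  }
})
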
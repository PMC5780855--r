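toy <- toy_fixture()

test_that("acceptance probability follows the exponential rule", {
  expect_equal(metropolis_probability(5, 4, c = 10), 1)   # improvement
  expect_equal(metropolis_probability(4, 4, c = 10), 1)   # neutral
  expect_equal(metropolis_probability(4, 5, c = 10), exp(-10))
  expect_equal(metropolis_probability(4, 6, c = 2), exp(-4))
  # probabilities always land in [0, 1]
  set.seed(1)
  for (i in 1:50) {
    p <- metropolis_probability(sample(0:20, 1), sample(0:20, 1),
                                c = runif(1, 0.1, 20))
    expect_gte(p, 0)
    expect_lte(p, 1)
  }
  expect_error(metropolis_probability(1, 2, c = -1),
               class = "tcoa_usage_error")
})

test_that("proposals keep untouched levels identical and matchings maximum", {
  set.seed(11)
  ldg <- build_linking_dynamic_graph(toy$network, toy$targets)
  state <- tcoa:::build_chain_state(toy$network,
                                    as.character(toy$targets),
                                    as.character(toy$constraints), ldg)
  seen_w <- integer(0)
  for (i in 1:40) {
    prop <- tcoa:::propose_rewire(state, toy$network,
                                  as.character(toy$targets),
                                  as.character(toy$constraints))
    if (is.null(prop)) next
    seen_w <- c(seen_w, prop$W)
    # every level of the proposal is a maximum matching of its level
    for (k in seq_len(prop$ldg$r)) {
      right_names <- toy$network$nodes[prop$ldg$levels[[k]]$level$right]
      expect_equal(prop$ldg$levels[[k]]$matching$size,
                   bf_matching_size(bf_level_adj(toy$network,
                                                 right_names)))
    }
    # level 0 always exists; matched targets stay matched in count
    expect_equal(prop$ldg$levels[[1]]$matching$size,
                 state$ldg$levels[[1]]$matching$size)
  }
  # from some state the chain reaches both W = 1 and W = 2 realisations
  expect_true(1L %in% seen_w)
})

test_that("prefix levels are carried over unchanged by a deep rewire", {
  set.seed(3)
  ldg <- ldg_from_matchings(toy$network, toy$targets,
                            toy_printed_matchings())
  state <- tcoa:::build_chain_state(toy$network,
                                    as.character(toy$targets),
                                    as.character(toy$constraints), ldg)
  deep_checked <- FALSE
  for (i in 1:100) {
    prop <- tcoa:::propose_rewire(state, toy$network,
                                  as.character(toy$targets),
                                  as.character(toy$constraints))
    if (is.null(prop)) next
    k0 <- prop$rewired_level
    for (k in seq_len(k0)) {
      expect_identical(prop$ldg$levels[[k]], state$ldg$levels[[k]])
    }
    if (k0 > 0) deep_checked <- TRUE
  }
  expect_true(deep_checked)
  # a level-2 rematch of the documented state must swap v3's predecessor
  m2 <- rematch_level(ldg, 2L, c("v1", "v3"), seed = 1)
  expect_false(is.null(m2))
  expect_true(matching_pairs(m2)[1, 1] %in% c("v2", "v4"))
})

test_that("the sampler is reproducible and its best weight non-increasing", {
  f1 <- tcoa(toy$network, toy$targets, toy$constraints, seed = 5,
             max_iter = 150, window = 50)
  f2 <- tcoa(toy$network, toy$targets, toy$constraints, seed = 5,
             max_iter = 150, window = 50)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$drivers, f2$drivers)
  expect_true(all(diff(f1$trace$W_best) <= 0))
  expect_equal(min(f1$trace$W), f1$W)
})

test_that("the toy optimum W = 1 with D = {v1} is found from any seed", {
  for (s in c(1, 2, 3, 42)) {
    fit <- tcoa(toy$network, toy$targets, toy$constraints, seed = s)
    expect_true(fit$feasible)
    expect_equal(fit$W, 1L)
    expect_equal(fit$drivers, "v1")
    expect_equal(fit$mu, 0L)
  }
})

test_that("control capacity counts driver membership over retained states", {
  sets <- list(c("a", "b"), c("a"), c("a", "c"))
  cap <- control_capacity(sets)
  expect_equal(cap$fd[cap$node == "a"], 1)
  expect_equal(cap$fd[cap$node == "b"], 1 / 3)
  expect_false("d" %in% cap$node)  # absent nodes simply do not appear
  expect_error(control_capacity(list()), class = "tcoa_usage_error")

  # on the toy the converged chain sits on the unique W = 1 optimum, so
  # v1's capacity approaches one as the window grows
  fit <- tcoa(toy_fixture()$network, toy_fixture()$targets,
              toy_fixture()$constraints, seed = 2, max_iter = 400,
              window = 200)
  expect_gt(fit$capacity$fd[fit$capacity$node == "v1"], 0.9)
  # optima-only counting restricts to best-weight states
  cap_opt <- control_capacity(fit, optima_only = TRUE)
  expect_equal(cap_opt$fd[cap_opt$node == "v1"], 1)
})

test_that("configuration invariants are enforced", {
  toy <- toy_fixture()
  expect_error(tcoa(toy$network, toy$targets, c = 0),
               class = "tcoa_usage_error")
  expect_error(tcoa(toy$network, toy$targets, window = 0),
               class = "tcoa_usage_error")
  expect_error(tcoa(toy$network, toy$targets, max_iter = 10, window = 50),
               class = "tcoa_usage_error")
  expect_error(tcoa(toy$network, character(0)),
               class = "tcoa_usage_error")
})
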
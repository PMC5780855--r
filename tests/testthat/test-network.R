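test_that("edge list parsing handles comments, CRLF, dedup and dialects", {
  path <- withr::local_tempfile()
  writeLines(c("# comment", "a\tb", "b\tc", "", "a\tb\r"), path)
  net <- suppressMessages(read_edge_list(path))
  expect_equal(length(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  expect_setequal(net$nodes, c("a", "b", "c"))

  # empty file -> empty network
  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  net0 <- read_edge_list(empty)
  expect_equal(unname(network_size(net0)), c(0L, 0L))

  # csv and whitespace dialects
  writeLines(c("x,y", "y,z"), path)
  expect_equal(nrow(read_edge_list(path, dialect = "csv")$edges), 2)
  writeLines(c("x y", "y  z"), path)
  expect_equal(nrow(read_edge_list(path, dialect = "whitespace")$edges), 2)
})

test_that("malformed lines and missing files are reported distinctly", {
  path <- withr::local_tempfile()
  writeLines(c("a\tb", "lonely"), path)
  expect_error(read_edge_list(path), "line 2")
  expect_error(read_edge_list(file.path(tempdir(), "nope-missing.tsv")),
               class = "tcoa_io_error")
  expect_error(read_edge_list(""), class = "tcoa_io_error")
})

test_that("undirected third-column edges expand to both orientations", {
  path <- withr::local_tempfile()
  writeLines(c("a\tb\tu", "b\tc"), path)
  net <- read_edge_list(path)
  en <- edge_names(net)
  keys <- paste(en[, 1], en[, 2])
  expect_setequal(keys, c("a b", "b a", "b c"))
})

test_that("write/read round trip preserves node and edge sets", {
  net <- synthetic_network("erdos_renyi", n = 15, l = 40, seed = 3)
  path <- withr::local_tempfile()
  write_edge_list(net, path)
  back <- read_edge_list(path)
  expect_setequal(back$nodes, intersect(net$nodes, c(edge_names(net))))
  expect_setequal(paste(edge_names(back)[, 1], edge_names(back)[, 2]),
                  paste(edge_names(net)[, 1], edge_names(net)[, 2]))
})

test_that("node lists deduplicate and report off-network identifiers", {
  net <- directed_network(cbind(c("a", "b"), c("b", "c")))
  path <- withr::local_tempfile()
  writeLines(c("x", "x", "y"), path)
  sub <- suppressMessages(read_node_list(path, net))
  expect_length(sub, 0)
  expect_setequal(attr(sub, "off_network"), c("x", "y"))

  writeLines(c("a", "a", "c", "zz"), path)
  sub <- suppressMessages(read_node_list(path, net, role = "target"))
  expect_setequal(as.character(sub), c("a", "c"))
  expect_equal(attr(sub, "off_network"), "zz")
  expect_equal(attr(sub, "role"), "target")

  writeLines(character(0), path)
  expect_length(suppressMessages(read_node_list(path, net)), 0)
})

test_that("expand_mixed_edges adds both orientations and is idempotent", {
  net <- directed_network(nodes = c("a", "b"))
  out <- expand_mixed_edges(net, cbind("a", "b"))
  en <- edge_names(out)
  expect_setequal(paste(en[, 1], en[, 2]), c("a b", "b a"))

  # already-present reverse edge: no duplicate; applying twice = once
  net2 <- directed_network(cbind("b", "a"))
  once <- expand_mixed_edges(net2, cbind("a", "b"))
  twice <- expand_mixed_edges(once, cbind("a", "b"))
  expect_equal(nrow(once$edges), 2)
  expect_identical(once$edges, twice$edges)
  expect_gte(nrow(once$edges), nrow(net2$edges))

  expect_error(expand_mixed_edges(net, cbind("a", "zz")),
               class = "tcoa_usage_error")
})

test_that("synthetic generators are seed-reproducible with exact ER counts", {
  a <- synthetic_network("erdos_renyi", n = 100, l = 150, seed = 1)
  b <- synthetic_network("erdos_renyi", n = 100, l = 150, seed = 1)
  expect_identical(a$edges, b$edges)
  c_ <- synthetic_network("erdos_renyi", n = 10, l = 90, seed = 7)
  expect_equal(nrow(c_$edges), 90)
  expect_error(synthetic_network("erdos_renyi", n = 5, l = 26, seed = 1),
               class = "tcoa_usage_error")

  sf1 <- synthetic_network("scale_free", n = 200, l = 400, seed = 5)
  sf2 <- synthetic_network("scale_free", n = 200, l = 400, seed = 5)
  expect_identical(sf1$edges, sf2$edges)
})

test_that("scale-free generator hits the requested degree exponent", {
  # maximum-likelihood power-law fit on out-degrees, averaged over
  # replicates, should land near the requested exponent
  fits <- vapply(1:5, function(s) {
    net <- synthetic_network("scale_free", n = 10000, l = 30000,
                             exponent_out = 2.5, exponent_in = 2.5,
                             seed = s)
    g <- igraph::graph_from_edgelist(net$edges, directed = TRUE)
    d <- igraph::degree(g, mode = "out")
    igraph::fit_power_law(d[d > 0], implementation = "plfit")$alpha
  }, 0)
  expect_lt(abs(mean(fits) - 2.5), 0.3)
})

test_that("the six-node fixture matches its documented structure", {
  toy <- toy_fixture()
  expect_setequal(as.character(toy$targets), c("v3", "v4", "v6"))
  expect_setequal(as.character(toy$constraints), "v1")
  en <- edge_names(toy$network)
  expect_setequal(paste(en[, 1], en[, 2]),
                  c("v1 v3", "v2 v3", "v4 v3", "v3 v4", "v3 v5", "v4 v5",
                    "v5 v6"))
  # full-network maximum matching has size 4 (brute force), so classical
  # full control needs N - |M| = 2 inputs
  adj <- bf_level_adj(toy$network, toy$network$nodes)
  expect_equal(bf_matching_size(adj), 4L)
})

test_that("duplicate edges are collapsed with a message", {
  expect_message(directed_network(rbind(c("a", "b"), c("a", "b"))),
                 "1 duplicate")
  net <- suppressMessages(directed_network(rbind(c("a", "b"), c("a", "b"))))
  expect_equal(nrow(net$edges), 1)
})
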
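test_that("degree centrality decomposes into input and output parts", {
  star <- pathway_graph(c("c", "l1", "l2", "l3", "l4"),
                        data.frame(source = "c", target = paste0("l", 1:4)))
  dc <- degree_centrality(star)
  expect_equal(dc[dc$id == "c", c("din", "dout", "dc")],
               data.frame(din = 0L, dout = 4L, dc = 4L), ignore_attr = TRUE)
  loop <- pathway_graph("x", data.frame(source = "x", target = "x"))
  expect_equal(unlist(degree_centrality(loop)[, c("din", "dout", "dc")]),
               c(din = 1L, dout = 1L, dc = 2L))
  g <- random_test_digraph(9)
  dc2 <- degree_centrality(g)
  expect_equal(sum(dc2$din), n_arcs(g))
  expect_equal(sum(dc2$dout), n_arcs(g))
})

test_that("closeness follows the directed formula and the disconnection convention", {
  p <- path_graph_abc()
  cc <- closeness_centrality(p, "out")
  expect_equal(cc$closeness[cc$id == "a"], 2 / 3)

  star <- pathway_graph(c("c", "l1", "l2", "l3"),
                        data.frame(source = "c", target = paste0("l", 1:3)))
  expect_equal(closeness_centrality(star, "out")$closeness[1L], 1)

  # two disjoint 2-cycles: r - 1 = 1, sum d = 1, N - 1 = 3
  two <- pathway_graph(c("a", "b", "c", "d"),
                       data.frame(source = c("a", "b", "c", "d"),
                                  target = c("b", "a", "d", "c")))
  expect_equal(closeness_centrality(two, "out")$closeness, rep(1 / 3, 4))
  expect_error(closeness_centrality(two, "out", strict = TRUE),
               "cannot reach")
})

test_that("strict and default closeness agree exactly on strongly connected graphs", {
  for (seed in 11:16) {
    set.seed(seed)
    n <- sample(4:12, 1)
    ids <- as.character(1:n)
    cyc <- data.frame(source = ids, target = ids[c(2:n, 1)])
    extra <- data.frame(source = sample(ids, 5, TRUE), target = sample(ids, 5, TRUE))
    g <- pathway_graph(ids, rbind(cyc, extra[extra$source != extra$target, ]))
    for (dir in c("out", "in", "all")) {
      expect_equal(closeness_centrality(g, dir)$closeness,
                   closeness_centrality(g, dir, strict = TRUE)$closeness)
    }
  }
})

test_that("betweenness matches the worked conventions", {
  p <- path_graph_abc()
  expect_equal(betweenness_centrality(p, "classic")$betweenness, c(0, 1, 0))
  expect_equal(betweenness_centrality(p, "directed")$betweenness, c(0, 0.5, 0))

  star <- pathway_graph(c("c", "l1", "l2", "l3"),
                        data.frame(source = "c", target = paste0("l", 1:3)))
  expect_equal(betweenness_centrality(star)$betweenness, rep(0, 4))

  ids <- as.character(1:4)  # complete digraph: no intermediaries
  all_pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  k4 <- pathway_graph(ids, all_pairs[all_pairs$source != all_pairs$target, ])
  expect_equal(betweenness_centrality(k4)$betweenness, rep(0, 4))

  expect_error(betweenness_centrality(pathway_graph(c("a", "b"))), "at least 3")
})

test_that("centralities equal brute-force matrix oracles on random digraphs", {
  for (seed in 201:230) {
    g <- random_test_digraph(seed, n_max = 20)
    n <- n_nodes(g)
    raw <- oracle_betweenness_raw(g)
    got <- betweenness_centrality(g, "directed")$betweenness
    expect_equal(got, unname(raw) / ((n - 1) * (n - 2)), tolerance = 1e-12)
    expect_equal(betweenness_centrality(g, "classic")$betweenness, 2 * got)
    for (dir in c("out", "in")) {
      expect_equal(closeness_centrality(g, dir)$closeness,
                   oracle_closeness(g, dir), tolerance = 1e-12)
    }
    expect_true(all(closeness_centrality(g, "out")$closeness >= 0))
    expect_true(all(closeness_centrality(g, "out")$closeness <= 1))
  }
})

test_that("raw betweenness agrees with igraph on random digraphs", {
  library(igraph)
  for (seed in 301:310) {
    g <- random_test_digraph(seed, n_max = 18)
    n <- n_nodes(g)
    ours <- betweenness_centrality(g, "directed")$betweenness * (n - 1) * (n - 2)
    theirs <- unname(igraph::betweenness(to_igraph(g), directed = TRUE))
    expect_equal(ours, theirs, tolerance = 1e-10)
  }
})

test_that("top_k ranks descending with ascending-id tie-breaks", {
  rec <- data.frame(id = c("c", "a", "b"), v = c(1, 3, 3))
  expect_equal(top_k(rec, "v", 2)$id, c("a", "b"))
  expect_equal(nrow(top_k(rec, "v", 10)), 3L)
  expect_equal(top_k(rec, "v", 10)$rank, 1:3)
  expect_error(top_k(rec, "zz", 2), "unknown metric")
  num <- data.frame(id = c("10", "2"), v = c(5, 5))
  expect_equal(top_k(num, "v", 2)$id, c("2", "10"))  # numeric id order
})
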
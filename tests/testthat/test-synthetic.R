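test_that("generators are deterministic given a seed and leave the RNG alone", {
  a <- make_bowtie_graph(lscc = 2, n_in = 3, n_out = 2, n_tendril = 2, seed = 5)
  b <- make_bowtie_graph(lscc = 2, n_in = 3, n_out = 2, n_tendril = 2, seed = 5)
  expect_identical(a, b)
  expect_identical(make_random_digraph(10, 0.3, seed = 2),
                   make_random_digraph(10, 0.3, seed = 2))
  expect_identical(make_kgml_fixture(n_ortholog = 5, n_activation = 3, seed = 3),
                   make_kgml_fixture(n_ortholog = 5, n_activation = 3, seed = 3))

  set.seed(123)
  before <- .Random.seed
  invisible(make_random_digraph(10, 0.3, seed = 99))
  expect_identical(before, .Random.seed)  # caller state restored
})

test_that("inconsistent bow-tie specs are rejected", {
  expect_error(make_bowtie_graph(lscc = 0), "lscc >= 1")
  expect_error(make_bowtie_graph(lscc = 1, n_tube = 1, n_in = 1), "tube")
  expect_error(make_bowtie_graph(lscc = 1, n_tendril = 2), "tendril")
  expect_error(make_bowtie_graph(lscc = 1, p_extra = 1.5), "p_extra")
})

test_that("planted bow-tie graphs are recovered exactly by the classifier", {
  sim <- make_bowtie_graph(lscc = 3, seed = 1)
  expect_equal(unname(bowtie_partition(sim$graph)$counts[["LSCC"]]), 3L)

  for (seed in 1:20) {
    set.seed(seed)
    n_in <- sample(0:8, 1)
    n_out <- sample(0:8, 1)
    spec <- list(
      lscc = sample(1:5, 1), n_in = n_in, n_out = n_out,
      n_tube = if (n_in > 0 && n_out > 0) sample(0:3, 1) else 0,
      n_tendril = if (n_in + n_out > 0) sample(0:5, 1) else 0,
      n_disconnected = sample(0:4, 1),
      p_extra = stats::runif(1, 0, 0.3)
    )
    sim <- do.call(make_bowtie_graph, c(spec, list(seed = 1000L + seed)))
    bt <- bowtie_partition(sim$graph)
    expect_identical(bt$role[names(sim$roles)], sim$roles)
  }
})

test_that("random digraphs hit their edge-probability envelope", {
  expect_equal(n_arcs(make_random_digraph(12, 0, seed = 1)), 0L)
  expect_equal(n_arcs(make_random_digraph(12, 1, seed = 1)), 12L * 11L)
  expect_equal(n_nodes(make_random_digraph(0, 0.5, seed = 1)), 0L)

  n <- 20; p <- 0.2; trials <- 30L
  m <- vapply(1:trials, function(s) n_arcs(make_random_digraph(n, p, seed = s)),
              integer(1))
  pairs <- as.numeric(n * (n - 1)) * trials
  expect_lt(abs(sum(m) - p * pairs), 3 * sqrt(pairs * p * (1 - p)))
})

test_that("KGML fixtures reproduce the declared inventory, including the full one", {
  fx <- make_kgml_fixture(n_ortholog = 59, n_compound = 16, n_map = 8,
                          n_group = 2, n_activation = 29, n_expression = 26,
                          n_inhibition = 6, seed = 21)
  ts <- summarize_topology(parse_kgml(fx$xml))
  expect_equal(ts$n_nodes, 85L)
  expect_equal(ts$n_lines, 61L)
  expect_equal(unname(ts$kind_counts),
               c(59L, 16L, 8L, 2L, 0L))
  expect_equal(unname(ts$class_counts), c(29L, 26L, 6L, 0L))

  rx <- make_kgml_fixture(n_ortholog = 3, n_compound = 4, n_activation = 2,
                          n_reaction = 2, seed = 8)
  ts2 <- summarize_topology(parse_kgml(rx$xml))
  expect_equal(ts2$n_lines, rx$manifest$m)
  expect_equal(unname(ts2$class_counts[["other"]]),
               unname(rx$manifest$class_counts[["other"]]))

  broken <- substr(fx$xml, 1, nchar(fx$xml) - 15L)
  expect_error(parse_kgml(broken), "malformed")
})

test_that("the synthetic pathway snapshot reproduces its documented aggregates", {
  g <- synthetic_hif_network()
  ts <- summarize_topology(g)
  expect_equal(ts$n_nodes, 85L)
  expect_equal(ts$n_lines, 61L)
  expect_equal(unname(ts$kind_counts), c(59L, 16L, 8L, 2L, 0L))
  expect_equal(unname(ts$class_counts), c(29L, 26L, 6L, 0L))

  tab <- component_table(weak_components(g))
  expect_equal(nrow(tab), 25L)
  expect_equal(sum(tab$size == 1L), 21L)
  expect_setequal(tab$size[tab$size > 1L], c(2L, 3L, 25L, 34L))
  # published representatives of the non-singleton subnets
  expect_equal(tab$representative[match(c(25L, 34L, 3L, 2L), tab$size)],
               c("5", "6", "9", "35"))

  core <- synthetic_hif_core()
  expect_equal(n_nodes(core), 34L)
  expect_equal(n_arcs(core), 34L)
  cs <- summarize_topology(core)
  expect_equal(unname(cs$class_counts), c(27L, 2L, 5L, 0L))
  expect_equal(unname(cs$kind_counts), c(24L, 9L, 0L, 1L, 0L))
})
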
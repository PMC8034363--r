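minimal_kgml <- function(body) {
  paste0('<?xml version="1.0"?><pathway name="path:ko00001" title="t">',
         body, "</pathway>")
}

test_that("minimal KGML documents parse with the stated kind/class mapping", {
  doc <- minimal_kgml(paste0(
    '<entry id="1" name="ko:K00001" type="ortholog"/>',
    '<entry id="2" name="ko:K00002" type="gene"/>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="activation" value="--"/></relation>'
  ))
  g <- parse_kgml(doc)
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_arcs(g), 1L)
  expect_equal(unname(summarize_topology(g)$class_counts[["activation"]]), 1L)
  expect_equal(g$nodes$kind, c("ortholog", "ortholog"))  # gene folds into ortholog

  m <- parse_kgml(minimal_kgml('<entry id="9" name="path:ko04066" type="map"/>'))
  expect_equal(n_nodes(m), 1L)
  expect_equal(n_arcs(m), 0L)
  expect_equal(m$nodes$kind, "map")
})

test_that("compound-subtype relations route through the compound node", {
  doc <- minimal_kgml(paste0(
    '<entry id="1" name="ko:K00001" type="ortholog"/>',
    '<entry id="2" name="ko:K00002" type="ortholog"/>',
    '<entry id="5" name="cpd:C00007" type="compound"/>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="compound" value="5"/>',
    '<subtype name="activation" value="--"/></relation>'
  ))
  g <- parse_kgml(doc)
  expect_equal(n_arcs(g), 2L)
  expect_setequal(paste(g$arcs$source, g$arcs$target), c("1 5", "5 2"))
  expect_equal(g$arcs$class, c("activation", "activation"))

  # missing compound entry: falls back to a direct arc
  doc2 <- minimal_kgml(paste0(
    '<entry id="1" name="ko:K00001" type="ortholog"/>',
    '<entry id="2" name="ko:K00002" type="ortholog"/>',
    '<relation entry1="1" entry2="2" type="PPrel">',
    '<subtype name="compound" value="99"/></relation>'
  ))
  g2 <- parse_kgml(doc2)
  expect_equal(paste(g2$arcs$source, g2$arcs$target), "1 2")
  expect_equal(g2$arcs$class, "other")
})

test_that("reaction elements become compound-mediated arcs of class other", {
  doc <- minimal_kgml(paste0(
    '<entry id="1" name="ko:K00001" type="ortholog" reaction="rn:R00001"/>',
    '<entry id="2" name="cpd:C00001" type="compound"/>',
    '<entry id="3" name="cpd:C00002" type="compound"/>',
    '<reaction id="1" name="rn:R00001" type="irreversible">',
    '<substrate id="2" name="cpd:C00001"/><product id="3" name="cpd:C00002"/>',
    '</reaction>'
  ))
  g <- parse_kgml(doc)
  expect_setequal(paste(g$arcs$source, g$arcs$target), c("2 1", "1 3"))
  expect_equal(unique(g$arcs$class), "other")
})

test_that("KGML parse errors are raised for malformed and inconsistent documents", {
  expect_error(parse_kgml("<pathway><entry id='1'"), "malformed")
  expect_error(parse_kgml("<notes><x/></notes>"), "expected <pathway>")
  expect_error(
    parse_kgml(minimal_kgml(paste0(
      '<entry id="1" name="ko:K1" type="ortholog"/>',
      '<relation entry1="1" entry2="77" type="PPrel"/>'
    ))),
    "1 -> 77"
  )
})

test_that("generated KGML fixtures parse back to their declared tallies", {
  fx <- make_kgml_fixture(n_ortholog = 12, n_compound = 3, n_map = 1,
                          n_activation = 9, n_expression = 4,
                          n_inhibition = 2, seed = 11)
  g <- parse_kgml(fx$xml)
  ts <- summarize_topology(g)
  expect_equal(ts$n_nodes, fx$manifest$n)
  expect_equal(ts$n_lines, fx$manifest$m)
  expect_equal(unname(ts$kind_counts), unname(fx$manifest$kind_counts))
  expect_equal(unname(ts$class_counts), unname(fx$manifest$class_counts))
  expect_equal(sum(ts$kind_counts), ts$n_nodes)
  expect_equal(sum(ts$class_counts), ts$n_lines)
})

test_that("Pajek reading covers labels, isolates, edges, comments and CRLF", {
  g <- read_pajek(c("*Vertices 2", '1 "a"', '2 "b"', "*Arcs", "1 2"))
  expect_equal(n_nodes(g), 2L)
  expect_equal(n_arcs(g), 1L)
  expect_equal(g$nodes$display_name, c("a", "b"))

  iso <- read_pajek(c("*Vertices 3", "*Arcs"))
  expect_equal(n_nodes(iso), 3L)
  expect_equal(n_arcs(iso), 0L)

  crlf <- paste0("% a comment\r\n*Vertices 2\r\n1 \"x y\"\r\n2\r\n",
                 "*Edges\r\n1 2\r\n")
  ge <- read_pajek(crlf)
  expect_equal(n_arcs(ge), 2L)  # an edge expands to two arcs
  expect_equal(ge$nodes$display_name[1L], "x y")

  expect_error(read_pajek(c("*Arcs", "1 2")), "missing \\*Vertices")
  expect_error(read_pajek(c("*Vertices 2", "*Arcs", "1 5")), "out of range")
})

test_that("Pajek writing is stable and round-trips random graphs", {
  expect_equal(write_pajek(pathway_graph())[1L], "*Vertices 0")
  loop <- pathway_graph("1", data.frame(source = "1", target = "1"))
  expect_true("1 1" %in% write_pajek(loop))

  for (seed in 1:15) {
    g <- random_test_digraph(seed)
    g2 <- read_pajek(write_pajek(g))
    expect_equal(n_nodes(g2), n_nodes(g))
    expect_setequal(paste(g2$arcs$source, g2$arcs$target),
                    paste(g$arcs$source, g$arcs$target))
    g3 <- read_pajek(write_pajek(g2))
    expect_equal(g3, g2)  # write∘read is the identity on read output
  }
})

test_that("TSV edge lists mirror the Pajek pair", {
  lines <- c("source\ttarget\tclass", "a\tb\tactivation", "b\tc\tinhibition")
  g <- read_edge_tsv(lines)
  expect_equal(n_nodes(g), 3L)
  expect_equal(g$arcs$class, c("activation", "inhibition"))
  expect_equal(read_edge_tsv(write_edge_tsv(g)), g)
  # header is optional
  expect_equal(n_arcs(read_edge_tsv("a\tb")), 1L)
})
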
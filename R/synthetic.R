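#' Generate a directed graph with a planted bow-tie structure
#'
#' Builds a graph whose bow-tie roles are known exactly by construction: core
#' nodes are wired into a directed cycle (a single core node gets a self-loop),
#' each IN node is given a path into the core (via the core or an
#' earlier-wired IN node, so the IN region stays acyclic), each OUT node a
#' path from it, tubes run from a random IN node to a random OUT node
#' bypassing the core, tendrils hang off IN (or feed into OUT), and
#' disconnected nodes are isolated. Optional extra arcs are planted only in
#' role-preserving positions (within the core, IN towards the core or towards
#' earlier IN nodes, core to OUT, earlier OUT to later OUT, IN to tubes,
#' tubes to OUT), so the returned role map stays exact. Deterministic for a
#' fixed seed.
#'
#' @param lscc Core size (`>= 1`).
#' @param n_in,n_out,n_tube,n_tendril,n_disconnected Role counts. Tubes
#'   require both IN and OUT nodes; tendrils require IN or OUT nodes.
#' @param p_extra Probability of each eligible extra arc, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A list with `graph` (a [pathway_graph()]) and `roles` (named
#'   character vector, the planted truth).
#' @examples
#' sim <- make_bowtie_graph(lscc = 1, n_in = 20, n_tendril = 13, seed = 42)
#' bowtie_partition(sim$graph)$counts
#' @export
make_bowtie_graph <- function(lscc = 1L, n_in = 0L, n_out = 0L, n_tube = 0L,
                              n_tendril = 0L, n_disconnected = 0L,
                              p_extra = 0, seed = NULL) {
  stopifnot(lscc >= 1L, n_in >= 0L, n_out >= 0L, n_tube >= 0L,
            n_tendril >= 0L, n_disconnected >= 0L)
  if (p_extra < 0 || p_extra > 1) stop("p_extra must be in [0, 1]")
  if (n_tube > 0L && (n_in == 0L || n_out == 0L)) {
    stop("tube nodes require both IN and OUT nodes")
  }
  if (n_tendril > 0L && n_in == 0L && n_out == 0L) {
    stop("tendril nodes require IN or OUT nodes")
  }
  core <- paste0("L", seq_len(lscc))
  ins <- if (n_in) paste0("I", seq_len(n_in)) else character(0)
  outs <- if (n_out) paste0("O", seq_len(n_out)) else character(0)
  tubes <- if (n_tube) paste0("P", seq_len(n_tube)) else character(0)
  tendrils <- if (n_tendril) paste0("T", seq_len(n_tendril)) else character(0)
  disc <- if (n_disconnected) paste0("D", seq_len(n_disconnected)) else character(0)
  ids <- c(core, ins, outs, tubes, tendrils, disc)
  roles <- stats::setNames(
    rep(c("LSCC", "IN", "OUT", "TUBE", "TENDRIL", "DISCONNECTED"),
        c(lscc, n_in, n_out, n_tube, n_tendril, n_disconnected)),
    ids
  )

  .with_seed(seed, {
    src <- character(0); tgt <- character(0)
    add <- function(s, t) {
      src <<- c(src, s); tgt <<- c(tgt, t)
    }
    if (lscc == 1L) add(core, core) else {
      add(core, c(core[-1L], core[1L]))
    }
    for (j in seq_len(n_in)) {
      pool <- c(core, ins[seq_len(j - 1L)])
      add(ins[j], pool[sample.int(length(pool), 1L)])
    }
    for (j in seq_len(n_out)) {
      pool <- c(core, outs[seq_len(j - 1L)])
      add(pool[sample.int(length(pool), 1L)], outs[j])
    }
    for (j in seq_len(n_tube)) {
      add(ins[sample.int(n_in, 1L)], tubes[j])
      add(tubes[j], outs[sample.int(n_out, 1L)])
    }
    in_side <- character(0)   # tendrils already attached below IN
    out_side <- character(0)  # tendrils already feeding into OUT
    for (j in seq_len(n_tendril)) {
      side <- if (n_in > 0L && n_out > 0L) sample(c("in", "out"), 1L)
              else if (n_in > 0L) "in" else "out"
      if (side == "in") {
        pool <- c(ins, in_side)
        add(pool[sample.int(length(pool), 1L)], tendrils[j])
        in_side <- c(in_side, tendrils[j])
      } else {
        pool <- c(outs, out_side)
        add(tendrils[j], pool[sample.int(length(pool), 1L)])
        out_side <- c(out_side, tendrils[j])
      }
    }
    if (p_extra > 0) {
      cand_s <- character(0); cand_t <- character(0)
      push <- function(s, t) {
        cand_s <<- c(cand_s, s); cand_t <<- c(cand_t, t)
      }
      if (lscc > 1L) for (a in core) for (b in core) if (a != b) push(a, b)
      for (j in seq_len(n_in)) {
        for (b in core) push(ins[j], b)
        if (j > 1L) for (k in seq_len(j - 1L)) push(ins[j], ins[k])
      }
      for (j in seq_len(n_out)) {
        for (a in core) push(a, outs[j])
        if (j > 1L) for (k in seq_len(j - 1L)) push(outs[k], outs[j])
      }
      for (p in tubes) {
        for (a in ins) push(a, p)
        for (b in outs) push(p, b)
      }
      if (length(cand_s)) {
        pick <- stats::runif(length(cand_s)) < p_extra
        add(cand_s[pick], cand_t[pick])
      }
    }
    graph <- pathway_graph(
      data.frame(id = ids, kind = "ortholog", stringsAsFactors = FALSE),
      data.frame(source = src, target = tgt, class = "activation",
                 stringsAsFactors = FALSE)
    )
    list(graph = graph, roles = roles)
  })
}

#' Generate a KGML fixture with a known tally manifest
#'
#' Writes a well-formed KGML document whose parse is guaranteed to yield
#' exactly the declared entry-kind and relation-class tallies: entries get
#' synthetic KO / compound / map accessions, relations are drawn over distinct
#' ordered entry pairs (so no arcs collapse), and optional reaction elements
#' add substrate -> enzyme -> product arc pairs of class `other`.
#'
#' @param n_ortholog,n_compound,n_map,n_group Entry counts by kind.
#' @param n_activation,n_expression,n_inhibition,n_other Relation counts by
#'   interaction class.
#' @param n_reaction Number of reaction elements (each needs an ortholog entry
#'   plus two compound entries; contributes 2 arcs of class `other`).
#' @param seed Optional integer seed.
#' @return A list with `xml` (a single string) and `manifest` (`n`, `m`,
#'   `kind_counts`, `class_counts`) describing the ground truth.
#' @examples
#' fx <- make_kgml_fixture(n_ortholog = 2, n_activation = 1, seed = 1)
#' summarize_topology(parse_kgml(fx$xml))$n_lines
#' @export
make_kgml_fixture <- function(n_ortholog = 0L, n_compound = 0L, n_map = 0L,
                              n_group = 0L, n_activation = 0L,
                              n_expression = 0L, n_inhibition = 0L,
                              n_other = 0L, n_reaction = 0L, seed = NULL) {
  stopifnot(n_ortholog >= 0L, n_compound >= 0L, n_map >= 0L, n_group >= 0L,
            n_activation >= 0L, n_expression >= 0L, n_inhibition >= 0L,
            n_other >= 0L, n_reaction >= 0L)
  n <- n_ortholog + n_compound + n_map + n_group
  n_rel <- n_activation + n_expression + n_inhibition + n_other
  if (n_rel > 0L && n < 2L) stop("relations need at least 2 entries")
  if (n_rel > n * (n - 1L)) stop("more relations than distinct ordered pairs")
  if (n_reaction > 0L && (n_ortholog < 1L || n_compound < 2L)) {
    stop("reactions need an ortholog entry and at least 2 compound entries")
  }

  kinds <- rep(c("ortholog", "compound", "map", "group"),
               c(n_ortholog, n_compound, n_map, n_group))
  ids <- as.character(seq_len(n))
  name_of <- function(kind, i) {
    switch(kind,
      ortholog = sprintf("ko:K%05d", i),
      compound = sprintf("cpd:C%05d", i),
      map = sprintf("path:ko%05d", i),
      group = "undefined"
    )
  }
  .with_seed(seed, {
    entries <- vapply(seq_len(n), function(i) {
      sprintf('  <entry id="%s" name="%s" type="%s"/>',
              ids[i], name_of(kinds[i], i), kinds[i])
    }, character(1))

    rel_classes <- rep(c("activation", "expression", "inhibition",
                         "binding/association"),
                       c(n_activation, n_expression, n_inhibition, n_other))
    rel_lines <- character(0)
    used <- character(0)
    if (n_rel > 0L) {
      rel_classes <- sample(rel_classes)
      for (cl in rel_classes) {
        repeat {
          pair <- sample.int(n, 2L)
          key <- paste(pair, collapse = "-")
          if (!key %in% used) break
        }
        used <- c(used, key)
        rel_lines <- c(rel_lines, sprintf(
          '  <relation entry1="%s" entry2="%s" type="PPrel">\n    <subtype name="%s" value="--"/>\n  </relation>',
          ids[pair[1L]], ids[pair[2L]], cl))
      }
    }

    rx_lines <- character(0)
    if (n_reaction > 0L) {
      enzymes <- which(kinds == "ortholog")
      cpds <- which(kinds == "compound")
      for (r in seq_len(n_reaction)) {
        e <- enzymes[sample.int(length(enzymes), 1L)]
        sp <- cpds[sample.int(length(cpds), 2L)]
        key1 <- paste(c(sp[1L], e), collapse = "-")
        key2 <- paste(c(e, sp[2L]), collapse = "-")
        if (key1 %in% used || key2 %in% used) next  # keep tallies exact
        used <- c(used, key1, key2)
        rx_lines <- c(rx_lines, sprintf(
          '  <reaction id="%s" name="rn:R%05d" type="irreversible">\n    <substrate id="%s" name="%s"/>\n    <product id="%s" name="%s"/>\n  </reaction>',
          ids[e], r, ids[sp[1L]], name_of("compound", sp[1L]),
          ids[sp[2L]], name_of("compound", sp[2L])))
      }
    }
    n_rx_arcs <- 2L * length(rx_lines)

    xml <- paste(c(
      '<?xml version="1.0"?>',
      '<pathway name="path:ko99999" org="ko" number="99999" title="synthetic fixture">',
      entries, rel_lines, rx_lines,
      "</pathway>"
    ), collapse = "\n")

    class_counts <- c(activation = n_activation, expression = n_expression,
                      inhibition = n_inhibition, other = n_other + n_rx_arcs)
    kind_counts <- c(ortholog = n_ortholog, compound = n_compound,
                     map = n_map, group = n_group, undefined = 0L)
    list(xml = xml,
         manifest = list(n = n, m = n_rel + n_rx_arcs,
                         kind_counts = kind_counts,
                         class_counts = class_counts))
  })
}

#' Generate an Erdos-Renyi style random digraph
#'
#' Each ordered pair of distinct nodes carries an arc independently with
#' probability `p` (self-loops excluded). Deterministic for a fixed seed.
#'
#' @param n Number of nodes (`>= 0`).
#' @param p Arc probability in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A [pathway_graph()] with ids `"1" .. "n"`.
#' @export
make_random_digraph <- function(n, p, seed = NULL) {
  stopifnot(n >= 0L, p >= 0, p <= 1)
  ids <- as.character(seq_len(n))
  if (n == 0L) return(pathway_graph())
  from <- rep(seq_len(n), each = n)
  to <- rep(seq_len(n), times = n)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  .with_seed(seed, {
    pick <- stats::runif(length(from)) < p
    pathway_graph(ids, data.frame(source = ids[from[pick]],
                                  target = ids[to[pick]],
                                  stringsAsFactors = FALSE))
  })
}
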
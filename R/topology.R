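#' Network density and average degree
#'
#' Density is the ratio of realised to possible connections. With self-loops
#' permitted the denominator is `n^2`; excluding loops it is `n*(n-1)`.
#' The average degree of a directed graph with `m` arcs is `2m/n` (each arc
#' contributes one in- and one out-endpoint).
#'
#' @param n Number of nodes.
#' @param m Number of arcs.
#' @param loops Should self-loops count as possible connections?
#' @return A single number.
#' @examples
#' graph_density(85, 61, loops = TRUE)   # 0.00844291
#' graph_density(85, 61, loops = FALSE)  # 0.00854342
#' average_degree(85, 61)                # 1.43529412
#' @export
graph_density <- function(n, m, loops = FALSE) {
  stopifnot(length(n) == 1L, length(m) == 1L, m >= 0)
  if (loops) {
    if (n < 1) stop("density with loops requires n >= 1")
    m / n^2
  } else {
    if (n < 2) stop("density without loops requires n >= 2")
    m / (n * (n - 1))
  }
}

#' @rdname graph_density
#' @export
average_degree <- function(n, m) {
  stopifnot(length(n) == 1L, length(m) == 1L, m >= 0)
  if (n < 1) stop("average degree requires n >= 1")
  2 * m / n
}

#' Geodesic distances, diameter and mean distance
#'
#' Geodesics follow arc direction (`mode = "out"`, distances from each node),
#' may be reversed (`"in"`) or computed on the undirected view (`"all"`).
#' The diameter is the longest finite geodesic over ordered pairs `i != j`;
#' the average distance is the mean over those finite geodesics (unreachable
#' pairs are excluded). When no ordered pair is reachable both are `NA` with a
#' warning rather than 0.
#'
#' @param graph A [pathway_graph()].
#' @param mode Direction convention for geodesics.
#' @return `geodesic_distances()` returns an `n x n` matrix (rows = sources)
#'   with `Inf` for unreachable pairs; `graph_diameter()` and
#'   `average_distance()` return a single number.
#' @examples
#' g <- pathway_graph(c("a", "b", "c"),
#'                    data.frame(source = c("a", "b"), target = c("b", "c")))
#' graph_diameter(g)     # 2
#' average_distance(g)   # 4/3
#' @export
geodesic_distances <- function(graph, mode = c("out", "in", "all")) {
  stopifnot(inherits(graph, "pathway_graph"))
  mode <- match.arg(mode)
  n <- n_nodes(graph)
  adj <- .adjacency(graph, mode)
  d <- matrix(Inf, n, n, dimnames = list(graph$nodes$id, graph$nodes$id))
  for (i in seq_len(n)) d[i, ] <- .bfs_dist(adj, i, n)
  d
}

#' @rdname geodesic_distances
#' @export
graph_diameter <- function(graph) {
  d <- .finite_offdiag(graph)
  if (!length(d)) {
    warning("no reachable ordered pair: diameter undefined")
    return(NA_real_)
  }
  max(d)
}

#' @rdname geodesic_distances
#' @export
average_distance <- function(graph) {
  d <- .finite_offdiag(graph)
  if (!length(d)) {
    warning("no reachable ordered pair: average distance undefined")
    return(NA_real_)
  }
  mean(d)
}

.finite_offdiag <- function(graph) {
  dm <- geodesic_distances(graph, "out")
  if (!nrow(dm)) return(numeric(0))
  off <- dm[row(dm) != col(dm)]
  off[is.finite(off)]
}

#' Topology summary of a pathway graph
#'
#' Collects the structural indicators reported for pathway networks: node and
#' line counts, density with and without self-loops, average degree, directed
#' diameter and mean geodesic distance, and tallies of node kinds and
#' interaction classes. Kind tallies always sum to `n`, class tallies to `m`.
#'
#' @param graph A [pathway_graph()].
#' @return An object of class `topology_summary` (a list).
#' @export
summarize_topology <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  n <- n_nodes(graph)
  m <- n_arcs(graph)
  dn <- if (n >= 2) graph_density(n, m, loops = FALSE) else NA_real_
  dl <- if (n >= 1) graph_density(n, m, loops = TRUE) else NA_real_
  ad <- if (n >= 1) average_degree(n, m) else NA_real_
  if (n > 0L && m > 0L) {
    diam <- suppressWarnings(graph_diameter(graph))
    avgd <- suppressWarnings(average_distance(graph))
  } else {
    diam <- NA_real_
    avgd <- NA_real_
  }
  structure(
    list(
      n_nodes = n,
      n_lines = m,
      density_no_loops = dn,
      density_with_loops = dl,
      avg_degree = ad,
      diameter = diam,
      avg_distance = avgd,
      degenerate = is.na(diam),
      kind_counts = .count_levels(graph$nodes$kind, .node_kinds),
      class_counts = .count_levels(graph$arcs$class, .arc_classes)
    ),
    class = "topology_summary"
  )
}

.count_levels <- function(x, levels) {
  out <- as.integer(table(factor(x, levels = levels)))
  names(out) <- levels
  out
}

#' @export
print.topology_summary <- function(x, ...) {
  cat("Topology summary\n")
  cat(sprintf("  nodes: %d   lines: %d\n", x$n_nodes, x$n_lines))
  cat(sprintf("  density: %.8f (loops) / %s (no loops)\n", x$density_with_loops,
              ifelse(is.na(x$density_no_loops), "NA",
                     sprintf("%.8f", x$density_no_loops))))
  cat(sprintf("  average degree: %s\n",
              ifelse(is.na(x$avg_degree), "NA", sprintf("%.8f", x$avg_degree))))
  cat(sprintf("  diameter: %s   mean distance: %s%s\n",
              ifelse(is.na(x$diameter), "NA", format(x$diameter)),
              ifelse(is.na(x$avg_distance), "NA", sprintf("%.5f", x$avg_distance)),
              if (x$degenerate) "   [degenerate: no reachable pair]" else ""))
  cat("  node kinds: ", paste(sprintf("%s %d", names(x$kind_counts), x$kind_counts),
                              collapse = ", "), "\n", sep = "")
  cat("  arc classes: ", paste(sprintf("%s %d", names(x$class_counts), x$class_counts),
                               collapse = ", "), "\n", sep = "")
  invisible(x)
}
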
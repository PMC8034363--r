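#' Weak-component decomposition
#'
#' A weak component is a maximal set of nodes mutually reachable when arc
#' direction is ignored — the "connected subnet" unit of cohesive-subgroup
#' analysis. Components are numbered by ascending representative (smallest
#' node id they contain). The minimum component size is 1: an isolated node is
#' its own subnet; components smaller than `min_size` are still reported but
#' flagged as below threshold.
#'
#' @param graph A [pathway_graph()].
#' @param min_size Reporting threshold (components below it are flagged, not
#'   dropped).
#' @return An object of class `component_partition`: a list with `assignment`
#'   (named integer, node id -> component number), `sizes`, `representative`
#'   and `min_size`.
#' @seealso [component_table()], [extract_largest()],
#'   [strongly_connected_components()]
#' @export
weak_components <- function(graph, min_size = 1L) {
  stopifnot(inherits(graph, "pathway_graph"), min_size >= 1L)
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- .adjacency(graph, "all")
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(adj[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  .component_partition(ids, comp, type = "weak", min_size = as.integer(min_size))
}

# shared packaging for weak/strong partitions: renumber components by
# ascending representative id
.component_partition <- function(ids, comp, type, min_size = 1L) {
  k <- max(comp, 0L)
  rep_idx <- vapply(seq_len(k), function(c) {
    members <- which(comp == c)
    members[.id_order(ids[members])[1L]]
  }, integer(1))
  new_order <- .id_order(ids[rep_idx])
  renum <- integer(k)
  renum[new_order] <- seq_len(k)
  comp <- renum[comp]
  assignment <- stats::setNames(comp, ids)
  sizes <- as.integer(table(factor(comp, levels = seq_len(k))))
  representative <- ids[rep_idx[new_order]]
  structure(
    list(assignment = assignment, sizes = sizes,
         representative = representative, type = type,
         min_size = min_size),
    class = "component_partition"
  )
}

#' @export
print.component_partition <- function(x, ...) {
  cat(sprintf("%s-component partition: %d component(s) over %d node(s)\n",
              if (identical(x$type, "strong")) "Strong" else "Weak",
              length(x$sizes), length(x$assignment)))
  if (length(x$sizes)) {
    cat(sprintf("  largest: %d node(s); smallest: %d\n", max(x$sizes), min(x$sizes)))
  }
  invisible(x)
}

#' Component distribution table
#'
#' One row per component: size, percent of all nodes (4 decimal places),
#' cumulative node count and percent, and the representative (smallest) node
#' id. Rows are ordered by representative ascending, so the cumulative columns
#' rise monotonically to 100.
#'
#' @param partition A [weak_components()] result.
#' @param n_total Total node count used for percentages (defaults to the
#'   partition's node count).
#' @return A data frame with columns `component`, `size`, `percent`, `cum_n`,
#'   `cum_percent`, `representative`, `below_min`.
#' @export
component_table <- function(partition, n_total = NULL) {
  stopifnot(inherits(partition, "component_partition"))
  n_total <- n_total %||% length(partition$assignment)
  if (n_total < 1L) {
    return(data.frame(component = integer(0), size = integer(0),
                      percent = numeric(0), cum_n = integer(0),
                      cum_percent = numeric(0), representative = character(0),
                      below_min = logical(0), stringsAsFactors = FALSE))
  }
  sizes <- partition$sizes
  data.frame(
    component = seq_along(sizes),
    size = sizes,
    percent = .round4(100 * sizes / n_total),
    cum_n = cumsum(sizes),
    cum_percent = .round4(100 * cumsum(sizes) / n_total),
    representative = partition$representative,
    below_min = sizes < (partition$min_size %||% 1L),
    stringsAsFactors = FALSE
  )
}

#' Extract the largest weak component (the core network)
#'
#' Returns the induced subgraph on the largest weak component. Ties are broken
#' by preferring the component with more induced arcs, then the one with the
#' smallest representative node id.
#'
#' @param graph A [pathway_graph()] with at least one node.
#' @return A [pathway_graph()].
#' @export
extract_largest <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  if (n_nodes(graph) < 1L) stop("extract_largest requires at least one node")
  part <- weak_components(graph)
  best <- which(part$sizes == max(part$sizes))
  if (length(best) > 1L) {
    arcs_in <- vapply(best, function(c) {
      members <- names(part$assignment)[part$assignment == c]
      sum(graph$arcs$source %in% members & graph$arcs$target %in% members)
    }, numeric(1))
    best <- best[arcs_in == max(arcs_in)]
    if (length(best) > 1L) {
      best <- best[.id_order(part$representative[best])[1L]]
    }
  }
  keep <- names(part$assignment)[part$assignment == best[1L]]
  .induced_subgraph(graph, keep)
}
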
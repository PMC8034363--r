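#' Degree centrality
#'
#' The overall degree centrality of a node is the number of its connections,
#' split into input and output degree: `DC = Din + Dout`. A self-loop counts
#' once on each side.
#'
#' @param graph A [pathway_graph()].
#' @return A data frame with columns `id`, `din`, `dout`, `dc`.
#' @seealso [closeness_centrality()], [betweenness_centrality()], [top_k()]
#' @export
degree_centrality <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  data.frame(
    id = graph$nodes$id,
    din = unname(degree_sequence(graph, "in")),
    dout = unname(degree_sequence(graph, "out")),
    dc = unname(degree_sequence(graph, "total")),
    stringsAsFactors = FALSE
  )
}

#' Closeness centrality with directed conventions
#'
#' On a strongly connected graph the closeness of node *i* is
#' `(N - 1) / sum_j d_ij`: the number of other nodes divided by the summed
#' geodesic distance to them. `direction = "out"` uses distances from *i*,
#' `"in"` distances towards *i*, `"all"` the undirected view.
#'
#' Pathway networks are rarely strongly connected, so by default unreachable
#' pairs are handled with the reachability-scaled convention
#' `CC_i = ((r_i - 1)/(N - 1)) * ((r_i - 1) / sum_{reachable j} d_ij)`,
#' where `r_i` counts the nodes reachable from (or to) *i* including itself.
#' On strongly connected graphs this equals the strict formula exactly. With
#' `strict = TRUE` the plain formula is used and any unreachable pair is an
#' error.
#'
#' @param graph A [pathway_graph()].
#' @param direction `"out"` (default), `"in"` or `"all"`.
#' @param strict Raise an error on disconnection instead of scaling?
#' @return A data frame with columns `id` and `closeness`.
#' @examples
#' g <- pathway_graph(c("a", "b", "c"),
#'                    data.frame(source = c("a", "b"), target = c("b", "c")))
#' closeness_centrality(g, "out")  # head node: 2/3
#' @export
closeness_centrality <- function(graph, direction = c("out", "in", "all"),
                                 strict = FALSE) {
  stopifnot(inherits(graph, "pathway_graph"))
  direction <- match.arg(direction)
  ids <- graph$nodes$id
  n <- length(ids)
  adj <- .adjacency(graph, direction)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    d <- .bfs_dist(adj, i, n)
    reach <- is.finite(d)
    r <- sum(reach)
    if (strict && r < n) {
      j <- which(!reach)[1L]
      stop(sprintf("strict closeness undefined: node %s cannot reach node %s",
                   ids[i], ids[j]))
    }
    if (n <= 1L || r <= 1L) {
      cc[i] <- 0
      next
    }
    sumd <- sum(d[reach])  # d[i] = 0 contributes nothing
    cc[i] <- if (strict) (n - 1) / sumd else ((r - 1) / (n - 1)) * ((r - 1) / sumd)
  }
  data.frame(id = ids, closeness = cc, stringsAsFactors = FALSE)
}

#' Betweenness centrality
#'
#' The betweenness of node *i* is the ratio of shortest paths passing through
#' it: `sum over pairs (j,k), j != i != k, of g_jk(i)/g_jk`, where `g_jk`
#' counts shortest directed paths from *j* to *k* and `g_jk(i)` those through
#' *i*; pairs with no path are skipped. The default `"classic"` normalization
#' divides by `(N-1)(N-2)/2` — the classical formula with its factor 2, as
#' centrality reports for these pathway networks print it even on directed
#' graphs; `"directed"` divides by `(N-1)(N-2)`, the conventional directed
#' scaling. Shortest paths are counted by breadth-first predecessor
#' accumulation over unit-length arcs.
#'
#' @param graph A [pathway_graph()] with at least 3 nodes.
#' @param normalization `"classic"` (factor 2, default) or `"directed"`.
#' @return A data frame with columns `id` and `betweenness`.
#' @examples
#' g <- pathway_graph(c("a", "b", "c"),
#'                    data.frame(source = c("a", "b"), target = c("b", "c")))
#' betweenness_centrality(g)  # middle node: 1
#' @export
betweenness_centrality <- function(graph, normalization = c("classic", "directed")) {
  stopifnot(inherits(graph, "pathway_graph"))
  normalization <- match.arg(normalization)
  ids <- graph$nodes$id
  n <- length(ids)
  if (n < 3L) stop("betweenness centrality requires at least 3 nodes")
  raw <- .betweenness_raw(.adjacency(graph, "out"), n)
  denom <- (n - 1) * (n - 2)
  bc <- if (normalization == "classic") 2 * raw / denom else raw / denom
  data.frame(id = ids, betweenness = bc, stringsAsFactors = FALSE)
}

# Brandes accumulation: raw[i] = sum over ordered pairs (s,t) of g_st(i)/g_st
.betweenness_raw <- function(adj, n) {
  raw <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- rep(list(integer(0)), n)
    order_visited <- integer(0)
    frontier <- s
    while (length(frontier)) {
      order_visited <- c(order_visited, frontier)
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      frontier <- unique(nxt)
    }
    delta <- numeric(n)
    for (w in rev(order_visited)) {
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
    }
    delta[s] <- 0
    raw <- raw + delta
  }
  raw
}

#' Combined centrality table
#'
#' Assembles degree, closeness (all three directions) and betweenness into one
#' record per node.
#'
#' @param graph A [pathway_graph()] (betweenness columns are `NA` when `n < 3`).
#' @param normalization Passed to [betweenness_centrality()].
#' @return A data frame with columns `id`, `din`, `dout`, `dc`, `cc_in`,
#'   `cc_out`, `cc_all`, `bc`.
#' @export
centrality_table <- function(graph, normalization = c("classic", "directed")) {
  stopifnot(inherits(graph, "pathway_graph"))
  normalization <- match.arg(normalization)
  out <- degree_centrality(graph)
  out$cc_in <- closeness_centrality(graph, "in")$closeness
  out$cc_out <- closeness_centrality(graph, "out")$closeness
  out$cc_all <- closeness_centrality(graph, "all")$closeness
  out$bc <- if (n_nodes(graph) >= 3L) {
    betweenness_centrality(graph, normalization)$betweenness
  } else {
    rep(NA_real_, n_nodes(graph))
  }
  out
}

#' Top-k ranking of a centrality table
#'
#' Orders records descending by the chosen metric, breaking ties by ascending
#' node id, and truncates to `k` rows (the full ranking when `k` exceeds the
#' record count).
#'
#' @param records A data frame with an `id` column and the metric column.
#' @param metric Name of the column to rank by.
#' @param k Number of rows to keep (`k >= 1`).
#' @return The ranked, truncated data frame with a leading `rank` column.
#' @export
top_k <- function(records, metric, k = 10L) {
  stopifnot(is.data.frame(records), !is.null(records$id), k >= 1L)
  if (!metric %in% names(records)) stop("unknown metric: ", metric)
  ord <- order(-records[[metric]], .id_rank(records$id))
  out <- records[ord, , drop = FALSE]
  out <- utils::head(out, k)
  rownames(out) <- NULL
  cbind(rank = seq_len(nrow(out)), out)
}
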
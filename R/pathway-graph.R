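#' Directed pathway graph
#'
#' `pathway_graph()` builds the directed, unweighted graph used throughout the
#' package. Nodes carry a `kind` drawn from the closed set
#' `{ortholog, compound, map, group, undefined}` (the element inventory of a
#' KEGG pathway map); arcs carry an `interaction class` drawn from
#' `{activation, expression, inhibition, other}`. The graph holds at most one
#' arc per ordered `(source, target)` pair: duplicate arc records are collapsed
#' and the first-declared class wins, so class tallies always sum to the line
#' count. Self-loops are permitted and count once towards in-degree and once
#' towards out-degree.
#'
#' @param nodes A data frame with column `id` (unique, coerced to character)
#'   and optional columns `kind`, `display_name` and `accessions`
#'   (space-separated database labels such as KO or compound numbers), or a
#'   character vector of ids. `NULL` gives an empty graph.
#' @param arcs A data frame with columns `source`, `target` and optionally
#'   `class`; endpoints must reference declared node ids. `NULL` gives a graph
#'   without arcs.
#' @return An object of class `pathway_graph`: a list with data frames
#'   `nodes` (`id`, `kind`, `display_name`, `accessions`) and `arcs`
#'   (`source`, `target`, `class`).
#' @examples
#' g <- pathway_graph(
#'   nodes = data.frame(id = c("1", "2"), kind = "ortholog"),
#'   arcs  = data.frame(source = "1", target = "2", class = "activation")
#' )
#' g
#' degree_sequence(g)
#' @seealso [degree_sequence()], [summarize_topology()], [parse_kgml()]
#' @export
pathway_graph <- function(nodes = NULL, arcs = NULL) {
  if (is.null(nodes)) {
    nodes <- data.frame(id = character(0), stringsAsFactors = FALSE)
  }
  if (is.character(nodes)) {
    nodes <- data.frame(id = nodes, stringsAsFactors = FALSE)
  }
  if (!is.data.frame(nodes) || (nrow(nodes) > 0L && is.null(nodes$id))) {
    stop("`nodes` must be a data frame with an `id` column or a character vector")
  }
  ids <- as.character(nodes$id %||% character(0))
  if (anyNA(ids) || any(!nzchar(ids))) stop("node ids must be non-missing, non-empty")
  if (anyDuplicated(ids)) {
    stop("duplicate node id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  kind <- as.character(nodes$kind %||% rep("undefined", length(ids)))
  kind[is.na(kind) | !nzchar(kind)] <- "undefined"
  bad <- setdiff(unique(kind), .node_kinds)
  if (length(bad)) stop("unknown node kind(s): ", paste(bad, collapse = ", "))
  display <- as.character(nodes$display_name %||% rep("", length(ids)))
  display[is.na(display)] <- ""
  acc <- as.character(nodes$accessions %||% rep("", length(ids)))
  acc[is.na(acc)] <- ""

  if (is.null(arcs) || NROW(arcs) == 0L) {
    arcs <- data.frame(source = character(0), target = character(0),
                       class = character(0), stringsAsFactors = FALSE)
  } else {
    if (!is.data.frame(arcs) || is.null(arcs$source) || is.null(arcs$target)) {
      stop("`arcs` must be a data frame with `source` and `target` columns")
    }
    src <- as.character(arcs$source)
    tgt <- as.character(arcs$target)
    cls <- as.character(arcs$class %||% rep("other", length(src)))
    cls[is.na(cls) | !nzchar(cls)] <- "other"
    badc <- setdiff(unique(cls), .arc_classes)
    if (length(badc)) stop("unknown interaction class(es): ", paste(badc, collapse = ", "))
    miss <- !(src %in% ids) | !(tgt %in% ids)
    if (any(miss)) {
      i <- which(miss)[1L]
      stop(sprintf("arc %s -> %s references an undeclared node", src[i], tgt[i]))
    }
    keep <- !duplicated(paste0(src, "\r", tgt))  # one line per ordered pair
    arcs <- data.frame(source = src[keep], target = tgt[keep], class = cls[keep],
                       stringsAsFactors = FALSE)
  }

  structure(
    list(
      nodes = data.frame(id = ids, kind = kind, display_name = display,
                         accessions = acc, stringsAsFactors = FALSE),
      arcs = arcs
    ),
    class = "pathway_graph"
  )
}

.node_kinds <- c("ortholog", "compound", "map", "group", "undefined")
.arc_classes <- c("activation", "expression", "inhibition", "other")

#' Numbers of nodes and arcs
#'
#' @param graph A [pathway_graph()].
#' @return A single integer.
#' @export
n_nodes <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  nrow(graph$nodes)
}

#' @rdname n_nodes
#' @export
n_arcs <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  nrow(graph$arcs)
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("Pathway graph: %d nodes, %d arcs (directed, unweighted)\n",
              n_nodes(x), n_arcs(x)))
  if (n_nodes(x) > 0L) {
    k <- table(factor(x$nodes$kind, levels = .node_kinds))
    cat("  node kinds: ", paste(sprintf("%s %d", names(k), k), collapse = ", "), "\n", sep = "")
  }
  if (n_arcs(x) > 0L) {
    a <- table(factor(x$arcs$class, levels = .arc_classes))
    cat("  arc classes:", paste(sprintf("%s %d", names(a), a), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.pathway_graph <- function(object, ...) summarize_topology(object)

#' Per-node degree sequence
#'
#' In- and out-degrees count arcs by their endpoint; a self-loop contributes 1
#' to the in-degree and 1 to the out-degree of its node (2 to the total), so
#' total degrees always sum to twice the number of arcs.
#'
#' @param graph A [pathway_graph()].
#' @param mode `"total"` (in + out, the default), `"in"` or `"out"`.
#' @return A named integer vector over all node ids (isolates get 0).
#' @export
degree_sequence <- function(graph, mode = c("total", "in", "out")) {
  stopifnot(inherits(graph, "pathway_graph"))
  mode <- match.arg(mode)
  ids <- graph$nodes$id
  outd <- as.integer(table(factor(graph$arcs$source, levels = ids)))
  ind <- as.integer(table(factor(graph$arcs$target, levels = ids)))
  deg <- switch(mode, total = ind + outd, `in` = ind, out = outd)
  names(deg) <- ids
  deg
}

# adjacency lists by node index; mode "all" is the undirected view
.adjacency <- function(graph, mode = c("out", "in", "all")) {
  mode <- match.arg(mode)
  ids <- graph$nodes$id
  n <- length(ids)
  si <- match(graph$arcs$source, ids)
  ti <- match(graph$arcs$target, ids)
  adj <- rep(list(integer(0)), n)
  pairs <- switch(mode,
    out = list(from = si, to = ti),
    `in` = list(from = ti, to = si),
    all = list(from = c(si, ti), to = c(ti, si))
  )
  if (length(pairs$from)) {
    sp <- split(pairs$to, pairs$from)
    idx <- as.integer(names(sp))
    for (k in seq_along(idx)) adj[[idx[k]]] <- unique(sp[[k]])
  }
  adj
}

# single-source BFS distances over an adjacency list; unreachable = Inf
.bfs_dist <- function(adj, start, n) {
  d <- rep(Inf, n)
  d[start] <- 0
  frontier <- start
  lev <- 0
  while (length(frontier)) {
    lev <- lev + 1
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.infinite(d[nxt])]
    d[nxt] <- lev
    frontier <- nxt
  }
  d
}

# induced subgraph on `keep_ids`, preserving node and arc order
.induced_subgraph <- function(graph, keep_ids) {
  nodes <- graph$nodes[graph$nodes$id %in% keep_ids, , drop = FALSE]
  arcs <- graph$arcs[graph$arcs$source %in% keep_ids &
                       graph$arcs$target %in% keep_ids, , drop = FALSE]
  rownames(nodes) <- NULL
  rownames(arcs) <- NULL
  pathway_graph(nodes, arcs)
}
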
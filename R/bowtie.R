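#' Strongly connected components
#'
#' Maximal sets of nodes with mutual directed reachability, computed by
#' Kosaraju's two-pass algorithm (iterative, so deep graphs do not overflow
#' the call stack). Singleton components are valid SCCs.
#'
#' @param graph A [pathway_graph()].
#' @return A `component_partition` (see [weak_components()]) with
#'   `type = "strong"`.
#' @export
strongly_connected_components <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- graph$nodes$id
  n <- length(ids)
  if (n == 0L) return(.component_partition(ids, integer(0), type = "strong"))
  out_adj <- .adjacency(graph, "out")
  in_adj <- .adjacency(graph, "in")

  # pass 1: finishing order by iterative DFS on the forward graph
  visited <- rep(FALSE, n)
  finish <- integer(0)
  for (root in seq_len(n)) {
    if (visited[root]) next
    stack_node <- root
    stack_next <- 1L
    visited[root] <- TRUE
    while (length(stack_node)) {
      top <- length(stack_node)
      v <- stack_node[top]
      nb <- out_adj[[v]]
      i <- stack_next[top]
      advanced <- FALSE
      while (i <= length(nb)) {
        w <- nb[i]
        i <- i + 1L
        if (!visited[w]) {
          stack_next[top] <- i
          stack_node <- c(stack_node, w)
          stack_next <- c(stack_next, 1L)
          visited[w] <- TRUE
          advanced <- TRUE
          break
        }
      }
      if (!advanced) {
        finish <- c(finish, v)
        stack_node <- stack_node[-top]
        stack_next <- stack_next[-top]
      }
    }
  }

  # pass 2: flood the reverse graph in reverse finishing order
  comp <- integer(n)
  cur <- 0L
  for (v in rev(finish)) {
    if (comp[v] > 0L) next
    cur <- cur + 1L
    frontier <- v
    comp[v] <- cur
    while (length(frontier)) {
      nxt <- unique(unlist(in_adj[frontier], use.names = FALSE))
      nxt <- nxt[comp[nxt] == 0L]
      comp[nxt] <- cur
      frontier <- nxt
    }
  }
  .component_partition(ids, comp, type = "strong")
}

.bowtie_roles <- c("LSCC", "IN", "OUT", "TUBE", "TENDRIL", "DISCONNECTED")
.bowtie_alias <- c(LSCC = "GSC", IN = "S", OUT = "P", DISCONNECTED = "IS")

#' Bow-tie macrostructure classification
#'
#' Partitions a directed network into the bow-tie roles: the selected largest
#' strongly connected component (`LSCC`), the input fan (`IN`: nodes that
#' reach the core but are not reachable from it), the output fan (`OUT`:
#' reachable from the core without reaching it), core-bypassing `TUBE` nodes
#' (reachable from IN and reaching OUT), `TENDRIL` nodes (hanging off IN or
#' into OUT, one side only) and `DISCONNECTED` nodes. In the metabolic
#' vocabulary LSCC/IN/OUT/DISCONNECTED are the giant strong component (GSC),
#' substrate subset (S), product subset (P) and isolated subset (IS).
#'
#' The core is the largest SCC by node count; ties prefer an SCC containing a
#' self-loop, then the smallest minimum node id. A singleton SCC is eligible —
#' signaling cores can be a single auto-regulated hub — but when the chosen
#' singleton carries no self-loop the result is flagged `degenerate`.
#'
#' @param graph A [pathway_graph()].
#' @return An object of class `bowtie_partition`: a list with `role` (named
#'   character, node id -> role), `counts` (over all six roles), `lscc_nodes`,
#'   `metabolic_alias`, and `degenerate`.
#' @examples
#' g <- make_bowtie_graph(lscc = 2, n_in = 1, n_out = 1, seed = 1)$graph
#' bowtie_partition(g)$counts
#' @export
bowtie_partition <- function(graph) {
  stopifnot(inherits(graph, "pathway_graph"))
  ids <- graph$nodes$id
  n <- length(ids)
  if (n == 0L) {
    return(structure(
      list(role = stats::setNames(character(0), character(0)),
           counts = stats::setNames(integer(length(.bowtie_roles)), .bowtie_roles),
           lscc_nodes = character(0), metabolic_alias = .bowtie_alias,
           degenerate = FALSE),
      class = "bowtie_partition"
    ))
  }
  scc <- strongly_connected_components(graph)
  comp <- scc$assignment[ids]
  sizes <- scc$sizes
  has_loop_id <- unique(graph$arcs$source[graph$arcs$source == graph$arcs$target])

  cand <- which(sizes == max(sizes))
  if (length(cand) > 1L) {
    with_loop <- vapply(cand, function(c) {
      any(ids[comp == c] %in% has_loop_id)
    }, logical(1))
    if (any(with_loop)) cand <- cand[with_loop]
    if (length(cand) > 1L) cand <- cand[.id_order(scc$representative[cand])[1L]]
  }
  core_comp <- cand[1L]
  lscc_idx <- which(comp == core_comp)
  lscc_nodes <- ids[lscc_idx]
  degenerate <- length(lscc_idx) == 1L && !(lscc_nodes %in% has_loop_id)

  out_adj <- .adjacency(graph, "out")
  in_adj <- .adjacency(graph, "in")
  from_core <- .multi_bfs(out_adj, lscc_idx, n)   # reachable from the core
  to_core <- .multi_bfs(in_adj, lscc_idx, n)      # reaching the core

  role <- rep("DISCONNECTED", n)
  role[lscc_idx] <- "LSCC"
  in_idx <- which(to_core & !from_core)
  role[in_idx] <- "IN"
  out_idx <- which(from_core & !to_core)
  role[out_idx] <- "OUT"
  rest <- which(role == "DISCONNECTED")
  if (length(rest)) {
    from_in <- .multi_bfs(out_adj, in_idx, n)
    to_out <- .multi_bfs(in_adj, out_idx, n)
    role[rest[from_in[rest] & to_out[rest]]] <- "TUBE"
    rest <- which(role == "DISCONNECTED")
    role[rest[from_in[rest] | to_out[rest]]] <- "TENDRIL"
  }

  counts <- .count_levels(role, .bowtie_roles)
  structure(
    list(role = stats::setNames(role, ids), counts = counts,
         lscc_nodes = lscc_nodes, metabolic_alias = .bowtie_alias,
         degenerate = degenerate),
    class = "bowtie_partition"
  )
}

# reachability from a seed set (logical vector); seeds themselves are TRUE
.multi_bfs <- function(adj, seeds, n) {
  seen <- rep(FALSE, n)
  if (!length(seeds)) return(seen)
  seen[seeds] <- TRUE
  frontier <- seeds
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  seen
}

#' @export
print.bowtie_partition <- function(x, ...) {
  cat("Bow-tie partition\n")
  for (r in .bowtie_roles) {
    if (x$counts[[r]] > 0L) {
      alias <- if (r %in% names(x$metabolic_alias)) {
        sprintf(" (%s)", x$metabolic_alias[[r]])
      } else ""
      cat(sprintf("  %-12s%s: %d\n", r, alias, x$counts[[r]]))
    }
  }
  if (x$degenerate) cat("  [degenerate core: loop-free singleton]\n")
  invisible(x)
}

#' Bow-tie report tables
#'
#' `summary`: one row per non-empty role in the order LSCC, IN, OUT, TUBE,
#' TENDRIL, DISCONNECTED with frequency, percent (4 decimal places),
#' cumulative columns and representative accessions. `nodes`: the per-node
#' listing (id, accessions, display name, kind, role).
#'
#' @param partition A [bowtie_partition()] result.
#' @param graph The [pathway_graph()] the partition was computed from.
#' @return A list with data frames `summary` and `nodes` and flag `degenerate`.
#' @export
bowtie_report <- function(partition, graph) {
  stopifnot(inherits(partition, "bowtie_partition"),
            inherits(graph, "pathway_graph"))
  ids <- graph$nodes$id
  if (!identical(sort(names(partition$role)), sort(ids))) {
    stop("partition does not match graph node set")
  }
  n <- length(ids)
  role <- partition$role[ids]
  rows <- lapply(.bowtie_roles, function(r) {
    cnt <- partition$counts[[r]]
    if (cnt == 0L) return(NULL)
    members <- ids[role == r]
    members <- members[.id_order(members)]
    acc <- graph$nodes$accessions[match(members, graph$nodes$id)]
    lab <- ifelse(nzchar(acc), acc, members)
    data.frame(role = r, n = cnt, percent = .round4(100 * cnt / n),
               representatives = paste(utils::head(lab, 3L), collapse = "; "),
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  summary$cum_n <- cumsum(summary$n)
  summary$cum_percent <- .round4(100 * summary$cum_n / n)
  summary <- summary[, c("role", "n", "percent", "cum_n", "cum_percent",
                         "representatives")]
  nodes <- data.frame(
    id = ids,
    accessions = graph$nodes$accessions,
    display_name = graph$nodes$display_name,
    kind = graph$nodes$kind,
    role = unname(role),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[.id_order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  list(summary = summary, nodes = nodes, degenerate = partition$degenerate)
}
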
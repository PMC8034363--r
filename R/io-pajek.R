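#' Read a Pajek .net network file
#'
#' Parses the Pajek `.net` dialect used for pathway network snapshots: a
#' `*Vertices N` header with optionally labelled vertices, then `*Arcs`
#' (directed) and/or `*Edges` sections; an edge line is expanded to two
#' opposite arcs. Lines beginning with `%` are comments; both LF and CRLF
#' endings are accepted. Vertex numbers become node ids (so the declared count
#' includes isolates) and quoted labels are preserved as `display_name`.
#'
#' @param x Path to a `.net` file, a single string, or a character vector of
#'   lines.
#' @return A [pathway_graph()] with `n` equal to the declared vertex count.
#' @examples
#' g <- read_pajek(c("*Vertices 2", '1 "a"', '2 "b"', "*Arcs", "1 2"))
#' n_nodes(g); n_arcs(g)
#' @seealso [write_pajek()]
#' @export
read_pajek <- function(x) {
  lines <- .text_lines(x)
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*%", lines) & nzchar(trimws(lines))
  lines <- trimws(lines[keep])
  if (!length(lines) || !grepl("^\\*vertices\\b", lines[1L], ignore.case = TRUE)) {
    stop("Pajek parse error: missing *Vertices header")
  }
  n <- suppressWarnings(as.integer(sub("^\\*vertices\\s+(\\d+).*$", "\\1",
                                       lines[1L], ignore.case = TRUE)))
  if (is.na(n) || n < 0L) stop("Pajek parse error: bad vertex count in header")

  section <- "vertices"
  labels <- as.character(seq_len(n))
  src <- integer(0); tgt <- integer(0)
  for (ln in lines[-1L]) {
    if (grepl("^\\*", ln)) {
      sec <- tolower(sub("^\\*(\\w+).*$", "\\1", ln))
      if (!sec %in% c("vertices", "arcs", "edges")) {
        stop("Pajek parse error: unsupported section *", sec)
      }
      section <- sec
      next
    }
    if (section == "vertices") {
      m <- regmatches(ln, regexec('^(\\d+)(?:\\s+"([^"]*)")?', ln))[[1L]]
      if (length(m) < 2L || !nzchar(m[2L])) {
        stop("Pajek parse error: bad vertex line: ", ln)
      }
      i <- as.integer(m[2L])
      if (i < 1L || i > n) stop("Pajek structural error: vertex index ", i,
                                " out of range 1..", n)
      if (length(m) >= 3L && nzchar(m[3L])) labels[i] <- m[3L]
    } else {
      f <- strsplit(ln, "\\s+")[[1L]]
      if (length(f) < 2L) stop("Pajek parse error: bad ", section, " line: ", ln)
      a <- suppressWarnings(as.integer(f[1L]))
      b <- suppressWarnings(as.integer(f[2L]))
      if (is.na(a) || is.na(b)) stop("Pajek parse error: bad ", section, " line: ", ln)
      if (a < 1L || a > n || b < 1L || b > n) {
        stop("Pajek structural error: vertex index out of range on line: ", ln)
      }
      if (section == "arcs") {
        src <- c(src, a); tgt <- c(tgt, b)
      } else {
        src <- c(src, a, b); tgt <- c(tgt, b, a)
      }
    }
  }
  nodes <- data.frame(id = as.character(seq_len(n)), display_name = labels,
                      stringsAsFactors = FALSE)
  arcs <- data.frame(source = as.character(src), target = as.character(tgt),
                     stringsAsFactors = FALSE)
  pathway_graph(nodes, arcs)
}

#' Write a pathway graph as Pajek .net text
#'
#' Vertices are written in ascending id order (numeric order when every id is
#' an integer) and renumbered 1..N as the format requires; the label is the
#' node's `display_name` when set, its id otherwise. Round-tripping a graph
#' read by [read_pajek()] reproduces an identical graph.
#'
#' @param graph A [pathway_graph()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @return Invisibly (or visibly when `path` is `NULL`), a character vector of
#'   `.net` lines.
#' @export
write_pajek <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  ord <- .id_order(graph$nodes$id)
  ids <- graph$nodes$id[ord]
  disp <- graph$nodes$display_name[ord]
  label <- ifelse(nzchar(disp), disp, ids)
  idx <- seq_along(ids)
  lines <- c(
    sprintf("*Vertices %d", length(ids)),
    sprintf('%d "%s"', idx, label),
    "*Arcs"
  )
  if (n_arcs(graph) > 0L) {
    s <- idx[match(graph$arcs$source, ids)]
    t <- idx[match(graph$arcs$target, ids)]
    lines <- c(lines, sprintf("%d %d", s, t))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read and write TSV edge lists
#'
#' The TSV dialect mirrors the Pajek pair: three tab-separated columns
#' `source`, `target`, `class` (class optional), with an optional header row.
#' Nodes are inferred from the endpoints in order of first appearance.
#'
#' @param x Path to a TSV file, a single string, or a character vector of lines.
#' @return `read_edge_tsv()` returns a [pathway_graph()]; `write_edge_tsv()`
#'   returns the lines as for [write_pajek()].
#' @export
read_edge_tsv <- function(x) {
  lines <- .text_lines(x)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^source\\t", tolower(lines[1L]))) {
    lines <- lines[-1L]
  }
  if (!length(lines)) return(pathway_graph())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stop("edge TSV parse error: line ", bad[1L], " has fewer than 2 fields")
  src <- vapply(parts, `[`, character(1), 1L)
  tgt <- vapply(parts, `[`, character(1), 2L)
  cls <- vapply(parts, function(p) if (length(p) >= 3L) p[3L] else "other", character(1))
  ids <- unique(c(rbind(src, tgt)))
  pathway_graph(ids, data.frame(source = src, target = tgt, class = cls,
                                stringsAsFactors = FALSE))
}

#' @rdname read_edge_tsv
#' @param graph A [pathway_graph()].
#' @param path Optional file path; when `NULL` the lines are returned.
#' @export
write_edge_tsv <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "pathway_graph"))
  lines <- c("source\ttarget\tclass",
             sprintf("%s\t%s\t%s", graph$arcs$source, graph$arcs$target,
                     graph$arcs$class))
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

# accept a file path, a single embedded-newline string, or a vector of lines
.text_lines <- function(x) {
  if (!is.character(x) || !length(x)) stop("expected a path or text")
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1L) return(strsplit(x, "\n", fixed = TRUE)[[1L]])
  x
}
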
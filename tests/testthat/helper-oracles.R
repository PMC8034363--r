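# Brute-force oracles, deliberately implemented via dense-matrix algebra so
# they share no code path with the package's BFS/Brandes/Kosaraju internals.

# 0/1 adjacency matrix in the graph's node order
oracle_adjacency <- function(graph) {
  ids <- graph$nodes$id
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n_arcs(graph) > 0L) {
    A[cbind(match(graph$arcs$source, ids), match(graph$arcs$target, ids))] <- 1
  }
  A
}

# all-pairs shortest directed distances by min-plus matrix powers
oracle_distances <- function(graph, mode = "out") {
  A <- oracle_adjacency(graph)
  if (mode == "in") A <- t(A)
  if (mode == "all") A <- pmax(A, t(A))
  n <- nrow(A)
  D <- matrix(Inf, n, n, dimnames = dimnames(A))
  if (n == 0L) return(D)
  diag(D) <- 0
  off <- row(D) != col(D)
  D[A > 0 & off] <- 1
  Rk <- A
  k <- 1
  while (k < n) {
    k <- k + 1
    Rk <- (Rk %*% A) > 0
    new <- Rk & !is.finite(D) & off
    if (!any(new)) break
    D[new] <- k
  }
  D
}

# shortest-path counts: walks of minimal length are exactly the shortest
# paths, so g_jk = (A^d_jk)[j, k]
oracle_path_counts <- function(graph) {
  A <- oracle_adjacency(graph)
  D <- oracle_distances(graph)
  n <- nrow(A)
  G <- matrix(0, n, n, dimnames = dimnames(A))
  if (n == 0L) return(list(D = D, G = G))
  powers <- vector("list", max(1, n))
  powers[[1]] <- A
  for (k in seq_len(n - 1)) powers[[k + 1]] <- powers[[k]] %*% A
  for (j in seq_len(n)) for (k in seq_len(n)) {
    d <- D[j, k]
    if (j != k && is.finite(d)) G[j, k] <- powers[[d]][j, k]
  }
  list(D = D, G = G)
}

# raw betweenness (sum over ordered pairs of g_jk(i)/g_jk) from path counts:
# g_jk(i) = g_ji * g_ik when d_ji + d_ik = d_jk
oracle_betweenness_raw <- function(graph) {
  pc <- oracle_path_counts(graph)
  D <- pc$D; G <- pc$G
  n <- nrow(D)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    through <- outer(G[, i], G[i, ])
    on_path <- is.finite(D) & (outer(D[, i], D[i, ], "+") == D)
    num <- through * on_path
    ratio <- ifelse(G > 0, num / pmax(G, 1), 0)
    ratio[i, ] <- 0
    ratio[, i] <- 0
    diag(ratio) <- 0
    raw[i] <- sum(ratio)
  }
  names(raw) <- rownames(D)
  raw
}

# reachability-scaled closeness evaluated directly from the oracle distances
oracle_closeness <- function(graph, direction = "out") {
  D <- oracle_distances(graph, direction)
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    d <- D[i, ]
    r <- sum(is.finite(d))
    if (n <= 1 || r <= 1) return(0)
    ((r - 1) / (n - 1)) * ((r - 1) / sum(d[is.finite(d)]))
  }, numeric(1))
}

# transitive closure by Warshall's algorithm (includes each node itself)
oracle_closure <- function(A) {
  n <- nrow(A)
  R <- A > 0
  if (n > 0) diag(R) <- TRUE
  for (k in seq_len(n)) R <- R | outer(R[, k], R[k, ])
  R
}

# SCC membership from mutual reachability of the closure
oracle_scc_membership <- function(graph) {
  A <- oracle_adjacency(graph)
  R <- oracle_closure(A)
  M <- R & t(R)
  n <- nrow(M)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    comp[M[i, ]] <- cur
  }
  stats::setNames(comp, graph$nodes$id)
}

oracle_weak_membership <- function(graph) {
  A <- oracle_adjacency(graph)
  R <- oracle_closure(pmax(A, t(A)))
  n <- nrow(R)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cur <- cur + 1L
    comp[R[i, ]] <- cur
  }
  stats::setNames(comp, graph$nodes$id)
}

# partitions agree iff the membership vectors are identical up to relabelling
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}

to_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    graph$arcs[, c("source", "target")],
    directed = TRUE,
    vertices = data.frame(name = graph$nodes$id)
  )
}

random_test_digraph <- function(seed, n_max = 25, p_max = 0.25) {
  set.seed(seed)
  n <- sample(3:n_max, 1)
  make_random_digraph(n, stats::runif(1, 0.02, p_max), seed = seed + 1000L)
}

path_graph_abc <- function() {
  pathway_graph(c("a", "b", "c"),
                data.frame(source = c("a", "b"), target = c("b", "c")))
}
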
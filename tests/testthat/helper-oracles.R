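# Independent brute-force oracles, deliberately naive and written without any
# reference to the package internals (or igraph).

# adjacency-matrix BFS: distances and shortest-path counts from source s
oracle_bfs <- function(adj, s) {
  n <- nrow(adj)
  dist <- rep(Inf, n); sigma <- rep(0, n)
  dist[s] <- 0; sigma[s] <- 1
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (u in frontier) {
      for (v in which(adj[u, ] == 1)) {
        if (is.infinite(dist[v])) { dist[v] <- dist[u] + 1; nxt <- c(nxt, v) }
        if (dist[v] == dist[u] + 1) sigma[v] <- sigma[v] + sigma[u]
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# normalized betweenness by explicit pair enumeration
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- lapply(seq_len(n), function(s) oracle_bfs(adj, s))
  bc <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v) next
      dst <- bfs[[s]]$dist[t]
      if (is.infinite(dst)) next
      if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst)
        tot <- tot + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
    }
    bc[v] <- tot
  }
  if (n > 2) bc / ((n - 1) * (n - 2) / 2) else rep(0, n)
}

# Wasserman-Faust closeness from BFS distances
oracle_closeness <- function(adj) {
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    d <- oracle_bfs(adj, v)$dist[-v]
    d <- d[is.finite(d)]
    r <- length(d) + 1
    if (r < 2 || n < 2) return(0)
    ((r - 1) / sum(d)) * ((r - 1) / (n - 1))
  }, numeric(1))
}

# MCC by exhaustive subset enumeration (fine for n <= 10)
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  is_clique <- function(idx) {
    if (length(idx) < 2) return(TRUE)
    all(adj[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))] == 1)
  }
  subsets <- unlist(lapply(2:n, function(k)
    utils::combn(n, k, simplify = FALSE)), recursive = FALSE)
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(cl) {
    !any(vapply(setdiff(seq_len(n), cl), function(v)
      is_clique(c(cl, v)), logical(1)))
  }, cliques)
  out <- numeric(n)
  for (cl in maximal) out[cl] <- out[cl] + factorial(length(cl) - 1)
  out
}

# AUROC by explicit case-control pair counting with half-credit ties
oracle_auroc <- function(score, positive) {
  cs <- score[positive]; ct <- score[!positive]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(cs) * length(ct))
}

# upper-tail hypergeometric by direct summation of the mass function
oracle_hyper_tail <- function(k, K, N, n) {
  js <- k:min(n, K)
  js <- js[js >= max(0, n - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# random simple graph as an adjacency matrix + matching igraph
random_graph_fixture <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    if (stats::runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("n", seq_len(n))
  list(adj = adj, graph = g)
}

# independent recursive minimal-depth walk over a plain tree
oracle_min_depth <- function(tree, p) {
  depths <- rep(Inf, p)
  max_depth <- 0
  walk <- function(node, depth) {
    max_depth <<- max(max_depth, depth)
    if (tree$split_var[node] > 0) {
      f <- tree$split_var[node]
      depths[f] <<- min(depths[f], depth)
      walk(tree$left[node], depth + 1)
      walk(tree$right[node], depth + 1)
    }
  }
  walk(1, 0)
  depths[is.infinite(depths)] <- max_depth + 1
  depths
}
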
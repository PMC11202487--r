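# Independent oracles used to cross-check the package implementations.
# They share no code with the functions they validate.

# Brute-force bounded simple-path count: enumerate every sequence of
# distinct vertices starting at `source` (no adjacency pruning while
# extending) and count those whose consecutive pairs are all adjacent.
# Exponential; small graphs only.
oracle_count_paths <- function(g, source, max_len) {
  nm <- igraph::V(g)$name
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  n <- length(nm)
  s <- match(as.character(source), nm)
  count <- 0L
  is_path <- function(seq_idx) {
    all(A[cbind(seq_idx[-length(seq_idx)], seq_idx[-1])] == 1)
  }
  extend <- function(seq_idx) {
    if (length(seq_idx) > max_len) return(invisible())
    for (v in seq_len(n)) {
      if (!(v %in% seq_idx)) {
        cand <- c(seq_idx, v)
        if (is_path(cand)) count <<- count + 1L
        if (length(cand) <= max_len) extend(cand)
      }
    }
  }
  extend(s)
  count
}

# Count bounded simple paths through igraph's own enumerator (independent
# C implementation of the same quantity).
igraph_count_paths <- function(g, source, max_len) {
  if (igraph::degree(g, source) == 0) return(0)
  paths <- igraph::all_simple_paths(g, from = source, cutoff = max_len)
  sum(lengths(paths) >= 2)
}

# Geodesic betweenness by explicit dynamic programming over BFS layers:
# sigma[s, v] = number of shortest s-v paths, accumulated pairwise.
oracle_betweenness <- function(g) {
  nm <- igraph::V(g)$name
  n <- length(nm)
  d <- igraph::distances(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    sigma[s, s] <- 1
    finite <- which(is.finite(d[s, ]))
    for (v in finite[order(d[s, finite])]) {
      if (v == s) next
      pred <- adj[[v]][d[s, adj[[v]]] == d[s, v] - 1]
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  bc <- setNames(numeric(n), nm)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in seq((s + 1), n)) {
        if (s == v || t == v || s == t) next
        if (!is.finite(d[s, t]) || sigma[s, t] == 0) next
        if (d[s, v] + d[v, t] == d[s, t])
          bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  bc
}

# Literal pair-by-pair Kendall tau-a.
oracle_kendall_a <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
      if (s > 0) conc <- conc + 1L
      if (s < 0) disc <- disc + 1L
    }
  }
  (conc - disc) / (n * (n - 1) / 2)
}

# Random test graph with roughly the requested mean degree.
random_test_graph <- function(n, target_degree, seed) {
  p <- min(1, target_degree / max(n - 1, 1))
  generate_graph("random_uniform", n, p = p, rng_seed = seed)
}
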
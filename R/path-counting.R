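# 0-based adjacency list for the C++ DFS.
adj_index_list <- function(g) {
  lapply(igraph::as_adj_list(g, mode = "all"),
         function(nb) as.integer(nb) - 1L)
}

# Warn (once per call) when the DFS search-tree bound suggests a very
# long run; the bound is n_edges * max_degree^(l-1).
check_path_budget <- function(g, max_len,
                              budget = getOption("cdpath.path_budget", 1e9)) {
  dmax <- if (igraph::vcount(g) == 0) 0 else max(igraph::degree(g))
  est <- igraph::ecount(g) * dmax^(max(max_len - 1, 0))
  if (is.finite(budget) && est > budget)
    warning(sprintf(paste0("bounded path count may be slow: work estimate ",
                           "%.3g exceeds budget %.3g (see option ",
                           "'cdpath.path_budget')"), est, budget))
  invisible(est)
}

#' Count simple paths of bounded length from a node
#'
#' Counts the simple paths (no repeated vertices) that start at `source`,
#' end at any other node, and have between 1 and `max_len` edges. Each
#' distinct vertex sequence counts once; this is the denominator of the
#' CDP score. Implemented as a depth-bounded DFS in C++.
#'
#' @param g An `igraph` object (undirected simple).
#' @param source Node label (or index) of the start node.
#' @param max_len Maximum path length in edges (`l`), at least 1.
#' @return A single count (numeric; counts can exceed integer range on
#'   dense graphs with large `l`).
#' @examples
#' g <- generate_graph("complete", 4)
#' count_bounded_simple_paths(g, "1", 3)   # 3 + 6 + 6 = 15
#' @export
count_bounded_simple_paths <- function(g, source, max_len) {
  g <- as_simple_undirected(g, warn = FALSE)
  if (!is.numeric(max_len) || length(max_len) != 1 || max_len < 1)
    stop("max_len must be a positive integer")
  idx <- match(as.character(source), igraph::V(g)$name)
  if (is.na(idx)) stop(sprintf("source node '%s' not in graph", source))
  check_path_budget(g, max_len)
  count_paths_source_cpp(adj_index_list(g), idx - 1L, as.integer(max_len))
}

#' Closed-form path count for `l = 2`
#'
#' For `max_len = 2` the bounded simple-path count from a node equals the
#' sum of its neighbours' degrees: each neighbour `y` contributes the
#' length-1 path to `y` plus `deg(y) - 1` length-2 continuations.
#'
#' @inheritParams count_bounded_simple_paths
#' @return A single count.
#' @examples
#' g <- generate_graph("cycle", 6)
#' count_l2_closed_form(g, "1")   # two neighbours of degree 2 -> 4
#' @export
count_l2_closed_form <- function(g, source) {
  g <- as_simple_undirected(g, warn = FALSE)
  v <- as.character(source)
  if (!v %in% igraph::V(g)$name)
    stop(sprintf("source node '%s' not in graph", source))
  deg <- igraph::degree(g)
  sum(deg[igraph::neighbors(g, v)$name])
}

#' Bounded simple-path counts for every node
#'
#' Batch version of [count_bounded_simple_paths()]: the count for each
#' node as source. Uses the neighbour-degree-sum closed form when
#' `max_len = 2`.
#'
#' @inheritParams count_bounded_simple_paths
#' @return A named numeric vector over all nodes.
#' @examples
#' count_all_sources(example_network(), 2)
#' @export
count_all_sources <- function(g, max_len) {
  g <- as_simple_undirected(g, warn = FALSE)
  if (!is.numeric(max_len) || length(max_len) != 1 || max_len < 1)
    stop("max_len must be a positive integer")
  nm <- igraph::V(g)$name
  if (max_len == 2) {
    deg <- igraph::degree(g)
    adj <- igraph::as_adj_list(g, mode = "all")
    counts <- vapply(adj, function(nb) sum(deg[as.integer(nb)]), numeric(1))
  } else {
    check_path_budget(g, max_len)
    counts <- count_paths_all_cpp(adj_index_list(g), as.integer(max_len))
  }
  setNames(as.numeric(counts), nm)
}
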
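#' The 12-node worked-example network
#'
#' A small social network of 12 users and 14 friendships used throughout
#' the documentation and tests as a worked example: under the CDP score
#' with path bound `l = 2`, node 3 outranks node 5 even though node 5 has
#' the higher degree.
#'
#' The construction is verified at build time against two constraint
#' sets: the degree sequence `3 2 3 2 4 1 2 3 1 2 3 2` for nodes 1..12,
#' and the per-node neighbour-degree sums `7 6 5 7 9 3 6 6 3 7 8 7`
#' (which, for `l = 2`, fully determine every node's simple-path count
#' and hence its CDP score). Any 12-node graph meeting both constraints
#' yields identical `l = 2` scores.
#'
#' @return An undirected simple `igraph` with nodes labelled `"1"`..`"12"`.
#' @examples
#' g <- example_network()
#' cdp(g, l = 2)
#' @export
example_network <- function() {
  edges <- c("3", "6",  "3", "9",  "1", "3",  "5", "4",
             "5", "10", "5", "12", "5", "11", "1", "2",
             "1", "7",  "2", "8",  "8", "4",  "8", "10",
             "7", "11", "11", "12")
  g <- igraph::make_graph(edges, directed = FALSE)
  g <- igraph::permute(g, match(igraph::V(g)$name, as.character(1:12)))
  deg <- igraph::degree(g)[as.character(1:12)]
  stopifnot(identical(unname(deg), c(3, 2, 3, 2, 4, 1, 2, 3, 1, 2, 3, 2)))
  nds <- vapply(as.character(1:12), function(v) {
    sum(igraph::degree(g)[igraph::neighbors(g, v)$name])
  }, numeric(1))
  stopifnot(identical(unname(nds), c(7, 6, 5, 7, 9, 3, 6, 6, 3, 7, 8, 7)))
  g
}

#' The Zachary karate-club network
#'
#' Loads the bundled canonical 34-node, 78-edge karate-club friendship
#' network (1-based node labels), the standard small benchmark for
#' influence ranking.
#'
#' @return An undirected simple `igraph`.
#' @examples
#' summarize_network(karate_network())
#' @export
karate_network <- function() {
  path <- system.file("extdata", "karate.edgelist", package = "cdpath",
                      mustWork = TRUE)
  load_edge_list(path)
}

#' Generate standard test-topology graphs
#'
#' Deterministic generators for the structured topologies used in the
#' test suite and two random families. Nodes are labelled `"1"`..`"n"`;
#' the star's hub is node `"1"`.
#'
#' @param kind One of `"complete"`, `"star"`, `"cycle"`, `"path"`,
#'   `"random_uniform"` (Erdős–Rényi G(n, p)) or
#'   `"preferential_attachment"` (Barabási–Albert, undirected).
#' @param n Number of nodes (total, including the star hub).
#' @param p Edge probability for `random_uniform`.
#' @param m Edges attached per step for `preferential_attachment`.
#' @param rng_seed Seed for the random families; the same seed always
#'   yields the same edge set. Ignored for deterministic kinds.
#' @return An undirected simple `igraph`.
#' @examples
#' generate_graph("star", 5)            # hub "1" plus 4 leaves
#' generate_graph("random_uniform", 30, p = 0.2, rng_seed = 1)
#' @export
generate_graph <- function(kind = c("complete", "star", "cycle", "path",
                                    "random_uniform",
                                    "preferential_attachment"),
                           n, p = NULL, m = 1, rng_seed = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != round(n))
    stop("n must be a positive integer")
  g <- switch(kind,
    complete = igraph::make_full_graph(n),
    star = igraph::make_star(n, mode = "undirected", center = 1),
    cycle = igraph::make_ring(n, circular = TRUE),
    path = igraph::make_ring(n, circular = FALSE),
    random_uniform = {
      if (is.null(p) || p < 0 || p > 1)
        stop("random_uniform needs edge probability p in [0, 1]")
      if (is.null(rng_seed)) igraph::sample_gnp(n, p)
      else with_seed(rng_seed, igraph::sample_gnp(n, p))
    },
    preferential_attachment = {
      if (m < 1) stop("preferential_attachment needs m >= 1")
      if (is.null(rng_seed)) igraph::sample_pa(n, m = m, directed = FALSE)
      else with_seed(rng_seed, igraph::sample_pa(n, m = m, directed = FALSE))
    })
  igraph::V(g)$name <- as.character(seq_len(n))
  as_simple_undirected(g, warn = FALSE)
}
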
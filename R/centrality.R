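#' Centrality result container
#'
#' Light S3 container pairing a named score vector with the measure name
#' and the parameters it was computed under, so that downstream tables
#' and comparisons stay self-describing.
#'
#' @param measure Measure name tag (e.g. `"cdp"`).
#' @param scores Named numeric vector, one finite score per node.
#' @param params Named list of parameters used.
#' @return An object of class `centrality_result`.
#' @export
centrality_result <- function(measure, scores, params = list()) {
  stopifnot(is.character(measure), length(measure) == 1,
            is.numeric(scores), !is.null(names(scores)))
  if (any(!is.finite(scores)))
    stop_numeric("non-finite scores in measure '%s'", measure)
  structure(list(measure = measure, params = params, scores = scores),
            class = "centrality_result")
}

#' @export
print.centrality_result <- function(x, ...) {
  p <- if (length(x$params) == 0) "" else
    paste0(" (", paste(names(x$params), unlist(x$params), sep = "=",
                       collapse = ", "), ")")
  cat(sprintf("<centrality_result> %s%s, %d nodes\n",
              x$measure, p, length(x$scores)))
  print(head(sort(x$scores, decreasing = TRUE), 6))
  invisible(x)
}

#' @export
as.data.frame.centrality_result <- function(x, ...) {
  ord <- score_order(x$scores)
  df <- data.frame(node = names(x$scores), score = unname(x$scores),
                   stringsAsFactors = FALSE)
  df$rank <- match(seq_len(nrow(df)), ord)
  df
}

#' CDP: centrality degree paths
#'
#' The CDP score of node `x` is `deg(x)^2 / P(x, l)`, where `deg(x)` is
#' the raw (unnormalized) degree and `P(x, l)` the number of simple paths
#' of length at most `l` starting at `x`
#' (see [count_bounded_simple_paths()]). Squaring the degree accentuates
#' hubs; dividing by the path count tempers nodes whose reach comes from
#' many redundant routes. An isolated node (degree 0, hence no paths) is
#' assigned score 0.
#'
#' @param g An `igraph` object (undirected simple).
#' @param l Maximum path length in edges; default 2, which looks one step
#'   past the immediate neighbourhood and is the usual operating point.
#' @return A `centrality_result`.
#' @examples
#' cdp(example_network(), l = 2)   # node 3 tops the ranking
#' @export
cdp <- function(g, l = 2) {
  g <- as_simple_undirected(g, warn = FALSE)
  deg <- igraph::degree(g)
  paths <- count_all_sources(g, l)
  scores <- ifelse(deg == 0, 0, deg^2 / paths)
  centrality_result("cdp", setNames(scores, igraph::V(g)$name),
                    params = list(l = l))
}

#' Degree centrality
#'
#' Raw degree, or degree divided by `N - 1` when `normalized = TRUE`.
#'
#' @param g An `igraph` object.
#' @param normalized Divide by `N - 1` (requires at least 2 nodes).
#' @return A `centrality_result`.
#' @export
degree_centrality <- function(g, normalized = FALSE) {
  g <- as_simple_undirected(g, warn = FALSE)
  deg <- igraph::degree(g)
  if (normalized) {
    n <- igraph::vcount(g)
    if (n < 2) stop("normalized degree centrality needs at least 2 nodes")
    deg <- deg / (n - 1)
  }
  centrality_result("degree", setNames(as.numeric(deg), igraph::V(g)$name),
                    params = list(normalized = normalized))
}

#' Closeness centrality
#'
#' For a connected graph, `(N - 1) / sum_j dist(v, j)` with geodesic
#' (BFS) distances. On disconnected graphs the classical form is
#' undefined; the default applies the Wasserman–Faust per-component
#' scaling `((r - 1) / (N - 1)) * ((r - 1) / sum dist)` where `r` is the
#' number of nodes reachable from `v` (including itself). Isolated nodes
#' score 0. `strict = TRUE` errors on disconnected input instead.
#'
#' @param g An `igraph` object.
#' @param strict Error when the graph is disconnected.
#' @return A `centrality_result`.
#' @export
closeness_centrality <- function(g, strict = FALSE) {
  g <- as_simple_undirected(g, warn = FALSE)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (n < 2) {
    warning("closeness undefined on a singleton graph; returning 0")
    return(centrality_result("closeness", setNames(0, nm)))
  }
  d <- igraph::distances(g)
  connected <- all(is.finite(d))
  if (!connected && strict)
    stop_numeric("graph is disconnected; closeness undefined in strict mode")
  scores <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    reach <- di[is.finite(di)]
    r <- length(reach) + 1              # nodes reachable, incl. self
    if (r < 2) return(0)                # isolated node
    ((r - 1) / (n - 1)) * ((r - 1) / sum(reach))
  }, numeric(1))
  centrality_result("closeness", setNames(scores, nm),
                    params = list(strict = strict))
}

#' Betweenness centrality
#'
#' Fraction of geodesics passing through each node, summed over unordered
#' pairs of distinct other nodes (Freeman's convention, endpoints never
#' counted as interior), unnormalized. Computed with Brandes'
#' accumulation as implemented in igraph.
#'
#' @param g An `igraph` object.
#' @return A `centrality_result`.
#' @examples
#' betweenness_centrality(generate_graph("star", 5))  # hub: 6
#' @export
betweenness_centrality <- function(g) {
  g <- as_simple_undirected(g, warn = FALSE)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  centrality_result("betweenness",
                    setNames(as.numeric(b), igraph::V(g)$name))
}

#' PageRank (unnormalized fixed-point form)
#'
#' Iterates `PR(v) <- (1 - damping) + damping * sum_{u ~ v} PR(u)/deg(u)`
#' from the all-ones vector until the maximum per-node change falls below
#' `tol`. In this form the scores average 1 and sum to `N` (the common
#' normalized PageRank multiplied by `N`). Each undirected edge acts as a
#' link in both directions; a degree-0 node receives the teleport term
#' `1 - damping` only.
#'
#' @param g An `igraph` object.
#' @param damping Damping factor in `[0, 1)`; default 0.85.
#' @param tol Convergence tolerance on the max per-node change.
#' @param max_iter Iteration cap; exceeding it raises an error carrying
#'   the residual.
#' @return A `centrality_result`.
#' @export
pagerank <- function(g, damping = 0.85, tol = 1e-10, max_iter = 1000) {
  if (damping < 0 || damping >= 1) stop("damping must lie in [0, 1)")
  g <- as_simple_undirected(g, warn = FALSE)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  deg <- igraph::degree(g)
  inv_deg <- ifelse(deg > 0, 1 / deg, 0)
  pr <- rep(1, n)
  for (it in seq_len(max_iter)) {
    nxt <- (1 - damping) + damping * as.numeric(A %*% (pr * inv_deg))
    resid <- max(abs(nxt - pr))
    pr <- nxt
    if (resid < tol)
      return(centrality_result("pagerank", setNames(pr, nm),
                               params = list(damping = damping, tol = tol,
                                             iterations = it)))
  }
  stop_numeric("pagerank did not converge in %d iterations (residual %.3g)",
               max_iter, resid, data = list(residual = resid))
}

#' Attribute-weighted degree centrality (CNA-GE form)
#'
#' `deg(v) * (alpha * expr(v) + beta * sum_{j ~ v} expr(j))`: degree
#' modulated by a per-node numeric attribute (originally a gene-expression
#' level) and the attribute mass of the neighbourhood. With an all-ones
#' attribute this reduces to `deg * (alpha + beta * deg)`.
#'
#' @param g An `igraph` object.
#' @param expr Named numeric vector of finite node attributes covering
#'   every node; default all ones.
#' @param alpha,beta Weights on own vs. neighbour attribute; default 0.5
#'   each.
#' @return A `centrality_result`.
#' @export
cna_ge <- function(g, expr = NULL, alpha = 0.5, beta = 0.5) {
  g <- as_simple_undirected(g, warn = FALSE)
  nm <- igraph::V(g)$name
  if (is.null(expr)) expr <- setNames(rep(1, length(nm)), nm)
  missing <- setdiff(nm, names(expr))
  if (length(missing) > 0)
    stop(sprintf("missing attribute values for node(s): %s",
                 paste(missing, collapse = ", ")))
  if (any(!is.finite(expr[nm]))) stop("attribute values must be finite")
  expr <- expr[nm]
  deg <- igraph::degree(g)
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  nbr_sum <- as.numeric(A %*% expr)
  scores <- as.numeric(deg) * (alpha * expr + beta * nbr_sum)
  centrality_result("cna_ge", setNames(scores, nm),
                    params = list(alpha = alpha, beta = beta))
}

#' Top-k nodes of a centrality result
#'
#' Nodes in descending score order; ties are broken by ascending node
#' label (numeric order when all labels are numeric). Requesting more
#' nodes than exist returns all of them with a warning.
#'
#' @param result A `centrality_result`, or a named numeric score vector.
#' @param k Number of nodes to return.
#' @return Character vector of node labels.
#' @examples
#' top_k(cdp(example_network()), 3)   # "3" "5" "8"
#' @export
top_k <- function(result, k) {
  scores <- if (inherits(result, "centrality_result")) result$scores
            else result
  stopifnot(is.numeric(scores), !is.null(names(scores)))
  if (k < 1) stop("k must be at least 1")
  if (k > length(scores)) {
    warning(sprintf("k = %d exceeds node count %d; returning all nodes",
                    k, length(scores)))
    k <- length(scores)
  }
  ord <- score_order(scores)
  names(scores)[ord][seq_len(k)]
}
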
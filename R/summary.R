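#' Whole-network topology summary
#'
#' Computes the descriptors conventionally reported for benchmark
#' networks: node and edge counts, average degree `2|E|/|V|`, the average
#' local clustering coefficient (a node with degree < 2 contributes 0),
#' and the degree assortativity (Pearson correlation of degrees at edge
#' endpoints). Assortativity is undefined when all endpoint degrees are
#' equal (e.g. a cycle) and is then reported as `NaN` rather than raising
#' an error.
#'
#' @param g An `igraph` object (coerced to undirected simple form).
#' @param name Optional network name carried into the summary.
#' @return An object of class `network_summary`: a list with fields
#'   `network`, `n_nodes`, `n_edges`, `avg_degree`, `avg_clustering`,
#'   `assortativity`.
#' @examples
#' summarize_network(generate_graph("complete", 5))   # C = 1, k = 4
#' summarize_network(karate_network())
#' @export
summarize_network <- function(g, name = "graph") {
  g <- as_simple_undirected(g, warn = FALSE)
  n <- igraph::vcount(g)
  if (n < 1) stop("graph must have at least one node")
  m <- igraph::ecount(g)
  cc <- if (m == 0) 0 else
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  r <- if (m == 0) NaN else
    suppressWarnings(igraph::assortativity_degree(g, directed = FALSE))
  if (is.na(r)) r <- NaN
  structure(list(network = name,
                 n_nodes = n,
                 n_edges = m,
                 avg_degree = 2 * m / n,
                 avg_clustering = cc,
                 assortativity = r),
            class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("Network summary: %s\n", x$network))
  cat(sprintf("  |V| = %d, |E| = %d, <k> = %.4g\n",
              x$n_nodes, x$n_edges, x$avg_degree))
  cat(sprintf("  avg clustering C = %.4f, assortativity r = %.4f\n",
              x$avg_clustering, x$assortativity))
  invisible(x)
}

#' @export
as.data.frame.network_summary <- function(x, ...) {
  data.frame(network = x$network, n_nodes = x$n_nodes, n_edges = x$n_edges,
             avg_clustering = x$avg_clustering,
             assortativity = x$assortativity,
             avg_degree = x$avg_degree,
             stringsAsFactors = FALSE)
}

#' Write a table of network summaries to CSV
#'
#' Columns, in order: `network`, `n_nodes`, `n_edges`, `avg_clustering`,
#' `assortativity`, `avg_degree`.
#'
#' @param summaries A `network_summary` or list of them.
#' @param path Output CSV path.
#' @return The combined data frame, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  if (inherits(summaries, "network_summary")) summaries <- list(summaries)
  df <- do.call(rbind, lapply(summaries, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}
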
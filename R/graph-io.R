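#' Coerce a graph to the package's working form
#'
#' All analyses in this package operate on undirected simple graphs with
#' named vertices. This helper enforces that contract: directed graphs are
#' symmetrized, self-loops and duplicate edges are dropped, and unnamed
#' vertices receive their 1-based index as label.
#'
#' @param g An `igraph` object.
#' @param warn Emit warnings when loops/duplicates are dropped or a
#'   directed graph is symmetrized.
#' @return An undirected simple `igraph` with a `name` vertex attribute.
#' @export
as_simple_undirected <- function(g, warn = TRUE) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) {
    if (warn) warning("directed graph symmetrized to undirected")
    g <- igraph::as_undirected(g, mode = "collapse")
  }
  n_loops <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loops > 0 && warn)
    warning(sprintf("dropped %d self-loop(s)", n_loops))
  if (n_multi > 0 && warn)
    warning(sprintf("collapsed %d duplicate edge(s)", n_multi))
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  igraph::V(g)$name <- as.character(igraph::V(g)$name)
  g
}

#' Read a graph from a plain edge list
#'
#' Each non-comment line must hold exactly two node labels separated by
#' whitespace or, with `delimiter = ","`, by commas. Labels are preserved
#' verbatim (integer-looking labels are not renumbered). Duplicate edges
#' are collapsed and self-loops dropped with a warning.
#'
#' @param path Path to the file. Lines starting with `#` are ignored.
#' @param delimiter Optional single-character delimiter; default splits on
#'   any run of whitespace or commas.
#' @return An undirected simple `igraph`.
#' @export
load_edge_list <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_parse("edge list file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  if (length(idx) == 0L) stop_parse("empty edge list: %s", path)
  split_re <- if (is.null(delimiter)) "[\\s,]+" else
    paste0("[", gsub("([\\^\\]\\\\-])", "\\\\\\1", delimiter), "\\s]+")
  ends <- matrix(NA_character_, nrow = length(idx), ncol = 2)
  for (i in seq_along(idx)) {
    tok <- strsplit(trimws(lines[idx[i]]), split_re, perl = TRUE)[[1]]
    tok <- tok[nzchar(tok)]
    if (length(tok) != 2L)
      stop_parse("line %d of %s: expected 2 tokens, found %d",
                 idx[i], path, length(tok))
    ends[i, ] <- tok
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = ends[, 1], to = ends[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
  as_simple_undirected(g)
}

#' Read a graph from a GML file
#'
#' Directed inputs are symmetrized with a warning; the result is an
#' undirected simple graph with labels taken from the GML `label` (or
#' `id`) field.
#'
#' @param path Path to a GML file.
#' @return An undirected simple `igraph`.
#' @export
load_gml <- function(path) {
  if (!file.exists(path)) stop_parse("GML file not found: %s", path)
  g <- tryCatch(igraph::read_graph(path, format = "gml"),
                error = function(e) stop_parse("cannot parse GML %s: %s",
                                               path, conditionMessage(e)))
  # Prefer the human label; fall back to the numeric id igraph stores.
  if (is.null(igraph::V(g)$name)) {
    lab <- igraph::V(g)$label
    if (is.null(lab)) lab <- igraph::V(g)$id
    if (!is.null(lab)) igraph::V(g)$name <- as.character(lab)
  }
  as_simple_undirected(g)
}

#' Read a graph from a Pajek .net file
#'
#' @param path Path to a Pajek file.
#' @return An undirected simple `igraph`.
#' @export
load_pajek <- function(path) {
  if (!file.exists(path)) stop_parse("Pajek file not found: %s", path)
  g <- tryCatch(igraph::read_graph(path, format = "pajek"),
                error = function(e) stop_parse("cannot parse Pajek %s: %s",
                                               path, conditionMessage(e)))
  if (is.null(igraph::V(g)$name) && !is.null(igraph::V(g)$id))
    igraph::V(g)$name <- as.character(igraph::V(g)$id)
  as_simple_undirected(g)
}

#' Load a graph, dispatching on file extension
#'
#' `.gml` goes to [load_gml()], `.net`/`.paj` to [load_pajek()], anything
#' else is treated as a plain edge list.
#'
#' @param path Input file.
#' @return An undirected simple `igraph`.
#' @export
load_graph <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         gml = load_gml(path),
         net = ,
         paj = load_pajek(path),
         load_edge_list(path))
}

#' Write a graph as a plain edge list
#'
#' One edge per line, two labels separated by a single space. Reading the
#' file back with [load_edge_list()] reproduces the same node and edge
#' sets.
#'
#' @param g An `igraph` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  g <- as_simple_undirected(g, warn = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  iso <- setdiff(igraph::V(g)$name, unique(c(el)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(iso) > 0)
    writeLines(paste("# isolated:", paste(iso, collapse = " ")), con)
  if (nrow(el) > 0)
    writeLines(paste(el[, 1], el[, 2]), con)
  invisible(path)
}

#' Write a graph in GML format
#'
#' @param g An `igraph` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gml <- function(g, path) {
  igraph::write_graph(as_simple_undirected(g, warn = FALSE), path,
                      format = "gml")
  invisible(path)
}
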
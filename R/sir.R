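#' SIR simulation parameters
#'
#' Configuration for the discrete-time stochastic
#' susceptible–infected–recovered process on a graph. At each step every
#' infected node independently tries to infect each susceptible
#' neighbour with probability `beta`; nodes infected at the start of a
#' step then recover with probability `lambda`. With `lambda = 1` a node
#' is infectious for exactly one step.
#'
#' @param beta Per-contact per-step infection probability in `[0, 1]`.
#' @param lambda Per-step recovery probability in `(0, 1]`; default 1.
#' @param runs Independent simulations per seed node; default 50.
#' @param max_steps Safety cap on steps per run (absorption is guaranteed
#'   with `lambda > 0`; the cap only guards pathological settings).
#' @param rng_seed Root seed; every `(source, run)` pair derives its own
#'   substream from it, so results do not depend on iteration order.
#' @return An object of class `sir_params`.
#' @export
sir_params <- function(beta, lambda = 1, runs = 50, max_steps = 10000,
                       rng_seed = 1) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0, beta <= 1,
            is.numeric(lambda), length(lambda) == 1, lambda > 0, lambda <= 1,
            is.numeric(runs), length(runs) == 1, runs >= 1,
            is.numeric(max_steps), max_steps >= 1,
            is.numeric(rng_seed), length(rng_seed) == 1)
  structure(list(beta = beta, lambda = lambda, runs = as.integer(runs),
                 max_steps = as.integer(max_steps),
                 rng_seed = as.integer(rng_seed)),
            class = "sir_params")
}

#' @export
print.sir_params <- function(x, ...) {
  cat(sprintf("<sir_params> beta=%g lambda=%g runs=%d max_steps=%d seed=%d\n",
              x$beta, x$lambda, x$runs, x$max_steps, x$rng_seed))
  invisible(x)
}

# Deterministic 31-bit seed for a (source index, run index) pair.
derive_seed <- function(root, source_idx, run) {
  (as.double(root) * 1000003 + source_idx * 7919 + run * 104729) %% 2147483647
}

# One synchronous SIR run from `source_idx` (1-based) on a prebuilt
# sparse adjacency matrix. States: 0 = S, 1 = I, 2 = R. Returns the
# number of nodes ever infected (seed included).
sir_run <- function(A, n, source_idx, beta, lambda, max_steps,
                    check_conservation = FALSE) {
  state <- integer(n)
  state[source_idx] <- 1L
  steps <- 0L
  while (any(state == 1L) && steps < max_steps) {
    inf <- state == 1L
    sus <- state == 0L
    if (beta > 0 && any(sus)) {
      # Number of infected neighbours of each node; a susceptible node
      # with k infected neighbours escapes all k independent attempts
      # with probability (1 - beta)^k.
      k <- as.numeric(A %*% as.numeric(inf))
      hit <- sus & k > 0 & runif(n) < 1 - (1 - beta)^k
    } else {
      hit <- logical(n)
    }
    recov <- inf & runif(n) < lambda
    state[hit] <- 1L
    state[recov] <- 2L
    if (check_conservation)
      stopifnot(sum(state == 0L) + sum(state == 1L) + sum(state == 2L) == n)
    steps <- steps + 1L
  }
  sum(state != 0L)
}

#' Single SIR run from one seed node
#'
#' Runs the synchronous discrete-time SIR process once, seeded at
#' `source`, and returns the cumulative number of nodes that were ever
#' infected (the seed counts; with `lambda = 1` this equals the final
#' recovered count, since no node stays infected at absorption).
#'
#' @param g An `igraph` object.
#' @param source Seed node label.
#' @param params An [sir_params()] object.
#' @param run Run index (selects the RNG substream).
#' @param check_conservation Assert `|S| + |I| + |R| = N` after every
#'   step (debug aid).
#' @return Count of ever-infected nodes, in `[1, N]`.
#' @export
sir_simulate_once <- function(g, source, params, run = 1,
                              check_conservation = FALSE) {
  stopifnot(inherits(params, "sir_params"))
  g <- as_simple_undirected(g, warn = FALSE)
  idx <- match(as.character(source), igraph::V(g)$name)
  if (is.na(idx)) stop(sprintf("source node '%s' not in graph", source))
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  n <- igraph::vcount(g)
  with_seed(derive_seed(params$rng_seed, idx, run),
            sir_run(A, n, idx, params$beta, params$lambda, params$max_steps,
                    check_conservation))
}

#' Per-node spreading efficiency under the SIR process
#'
#' Seeds the SIR process at every node in turn, repeats each seeding
#' `params$runs` times on independent RNG substreams, and averages the
#' ever-infected counts. The mean count is the node's spreading
#' efficiency — the ground truth against which centrality rankings are
#' validated. Results are reproducible bit-for-bit given the graph and
#' parameters, regardless of evaluation order.
#'
#' @param g An `igraph` object.
#' @param params An [sir_params()] object.
#' @param per_run Keep the per-run counts matrix (runs x nodes).
#' @return An object of class `spread_result`: list with `efficiency`
#'   (named numeric, mean ever-infected per seed node), `sd` (per-node
#'   standard deviation across runs), `params`, and optionally
#'   `per_run_counts`.
#' @examples
#' g <- example_network()
#' sr <- spreading_efficiency(g, sir_params(beta = 0.3, runs = 20))
#' sort(sr$efficiency, decreasing = TRUE)[1:3]
#' @export
spreading_efficiency <- function(g, params, per_run = FALSE) {
  stopifnot(inherits(params, "sir_params"))
  g <- as_simple_undirected(g, warn = FALSE)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  A <- igraph::as_adjacency_matrix(g, sparse = TRUE)
  counts <- matrix(NA_real_, nrow = params$runs, ncol = n)
  for (i in seq_len(n)) {
    for (r in seq_len(params$runs)) {
      counts[r, i] <- with_seed(
        derive_seed(params$rng_seed, i, r),
        sir_run(A, n, i, params$beta, params$lambda, params$max_steps))
    }
  }
  eff <- setNames(colMeans(counts), nm)
  sds <- setNames(apply(counts, 2, stats::sd), nm)
  out <- list(efficiency = eff, sd = sds, params = params)
  if (per_run) {
    colnames(counts) <- nm
    out$per_run_counts <- counts
  }
  structure(out, class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("<spread_result> %d nodes, beta=%g lambda=%g runs=%d\n",
              length(x$efficiency), x$params$beta, x$params$lambda,
              x$params$runs))
  print(head(sort(x$efficiency, decreasing = TRUE), 6))
  invisible(x)
}

#' Epidemic-threshold reference value for beta
#'
#' Returns the classical mean-field epidemic threshold
#' `<k> / (<k^2> - <k>)` of the degree distribution — a conventional
#' reference point for choosing the infection probability, not a
#' prescription. Callers still set `beta` explicitly.
#'
#' @param g An `igraph` object.
#' @return The threshold estimate (single numeric).
#' @examples
#' suggest_beta(generate_graph("complete", 4))   # 1/2
#' @export
suggest_beta <- function(g) {
  g <- as_simple_undirected(g, warn = FALSE)
  deg <- igraph::degree(g)
  k1 <- mean(deg)
  k2 <- mean(deg^2)
  if (k2 <= k1)
    stop_numeric("epidemic threshold undefined: <k^2> = %.3g <= <k> = %.3g",
                 k2, k1)
  k1 / (k2 - k1)
}
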
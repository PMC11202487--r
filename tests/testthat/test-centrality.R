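# Truncate (not round) to two decimals, the convention used when
# comparing against the worked-example score table.
trunc2 <- function(x) trunc(x * 100) / 100

test_that("CDP reproduces the worked-example scores after truncation", {
  g <- example_network()
  r <- cdp(g, l = 2)
  expect_equal(unname(trunc2(r$scores[as.character(1:12)])),
               c(1.28, 0.66, 1.8, 0.57, 1.77, 0.33, 0.66, 1.5, 0.33, 0.57,
                 1.12, 0.57))
  expect_identical(top_k(r, 3), c("3", "5", "8"))
})

test_that("CDP takes its analytic values on symmetric topologies", {
  for (n in 3:8)
    expect_equal(unname(cdp(generate_graph("complete", n))$scores),
                 rep(1, n))
  for (n in 4:9)
    expect_equal(unname(cdp(generate_graph("cycle", n))$scores), rep(1, n))
  # star with n leaves: hub n^2/n = n, leaf 1/n
  s <- cdp(generate_graph("star", 7))$scores     # hub "1", 6 leaves
  expect_equal(unname(s["1"]), 6)
  expect_equal(unname(s[names(s) != "1"]), rep(1 / 6, 6))
  # isolated node scores 0
  g <- igraph::add_vertices(example_network(), 1, name = "iso")
  expect_equal(unname(cdp(g)$scores["iso"]), 0)
})

test_that("CDP is invariant under node relabeling", {
  g <- random_test_graph(18, 4, seed = 42)
  base <- cdp(g, l = 3)$scores
  for (seed in 1:3) {
    perm <- local({ set.seed(seed); sample(igraph::vcount(g)) })
    g2 <- igraph::permute(g, perm)
    expect_equal(cdp(g2, l = 3)$scores[names(base)], base)
  }
})

test_that("CDP via DFS equals CDP via the brute-force path oracle", {
  for (seed in 1:5) {
    g <- random_test_graph(9, 3, seed = 200 + seed)
    l <- (seed %% 3) + 2
    deg <- igraph::degree(g)
    expected <- vapply(igraph::V(g)$name, function(v) {
      p <- oracle_count_paths(g, v, l)
      if (deg[v] == 0) 0 else unname(deg[v])^2 / p
    }, numeric(1))
    expect_equal(cdp(g, l = l)$scores, expected)
  }
})

test_that("degree centrality: raw, normalized and edge cases", {
  g <- example_network()
  raw <- degree_centrality(g)$scores
  expect_equal(unname(raw["5"]), 4)
  expect_equal(names(which.max(raw)), "5")

  k6 <- generate_graph("complete", 6)
  expect_equal(unname(degree_centrality(k6, normalized = TRUE)$scores),
               rep(1, 6))
  gi <- igraph::add_vertices(g, 1, name = "iso")
  expect_equal(unname(degree_centrality(gi)$scores["iso"]), 0)
  singleton <- igraph::make_empty_graph(1, directed = FALSE)
  expect_error(degree_centrality(singleton, normalized = TRUE), "2 nodes")
})

test_that("closeness centrality: analytic values and disconnected handling", {
  expect_equal(unname(closeness_centrality(generate_graph("star", 5))$scores["1"]),
               1)
  p3 <- generate_graph("path", 3)
  expect_equal(unname(closeness_centrality(p3)$scores["1"]), 2 / 3)
  expect_equal(unname(closeness_centrality(generate_graph("complete", 5))$scores),
               rep(1, 5))

  # two components: per-component Wasserman-Faust scaling
  g2 <- igraph::make_graph(c("1","2", "1","3", "2","3", "4","5"),
                           directed = FALSE)
  sc <- closeness_centrality(g2)$scores
  expect_equal(unname(sc["1"]), (2 / 4) * (2 / 2))   # r=3, N=5, dist sum 2
  expect_equal(unname(sc["4"]), (1 / 4) * (1 / 1))
  expect_error(closeness_centrality(g2, strict = TRUE),
               class = "cdpath_numeric_error")
  expect_warning(closeness_centrality(igraph::make_empty_graph(1)),
                 "singleton")
})

test_that("betweenness centrality matches analytic values and the DP oracle", {
  expect_equal(unname(betweenness_centrality(generate_graph("star", 5))$scores["1"]),
               6)
  expect_equal(unname(betweenness_centrality(generate_graph("complete", 6))$scores),
               rep(0, 6))
  expect_equal(unname(betweenness_centrality(generate_graph("cycle", 4))$scores),
               rep(0.5, 4))
  for (seed in 1:4) {
    g <- random_test_graph(15, 4, seed = 300 + seed)
    expect_equal(betweenness_centrality(g)$scores, oracle_betweenness(g),
                 tolerance = 1e-10)
  }
})

test_that("pagerank satisfies its fixed-point contract", {
  for (g in list(generate_graph("complete", 5), generate_graph("cycle", 8))) {
    pr <- pagerank(g)
    expect_equal(unname(pr$scores), rep(1, igraph::vcount(g)),
                 tolerance = 1e-8)
  }
  g <- karate_network()
  pr <- pagerank(g, tol = 1e-12)
  n <- igraph::vcount(g)
  expect_lt(abs(sum(pr$scores) - n), 10 * 1e-12 * n)
  # agrees with igraph's independent implementation (x N rescaling)
  ig <- igraph::page_rank(g, damping = 0.85)$vector * n
  expect_equal(pr$scores, ig, tolerance = 1e-6)

  s5 <- pagerank(generate_graph("star", 5))
  expect_true(s5$scores["1"] > max(s5$scores[-1]))
  expect_equal(unname(s5$scores[2]), unname(s5$scores[3]))

  err <- tryCatch(pagerank(g, max_iter = 1), cdpath_numeric_error = identity)
  expect_s3_class(err, "cdpath_numeric_error")
  expect_true(is.numeric(err$data$residual))
})

test_that("attribute-weighted degree follows its formula", {
  k4 <- generate_graph("complete", 4)
  expect_equal(unname(cna_ge(k4)$scores), rep(6, 4))  # 0.5*3*(1+3)
  g <- example_network()
  expr <- setNames(seq_len(12) / 10, as.character(1:12))
  r <- cna_ge(g, expr, alpha = 1, beta = 0)
  expect_equal(r$scores, igraph::degree(g) * expr[names(r$scores)])
  gi <- igraph::add_vertices(g, 1, name = "iso")
  expect_equal(unname(cna_ge(gi, c(expr, iso = 5))$scores["iso"]), 0)
  expect_error(cna_ge(g, expr[-3]), "missing attribute.*3")
})

test_that("top_k orders by score with label tie-break", {
  scores <- setNames(c(2, 2, 2, 1), c("10", "9", "2", "1"))
  expect_identical(top_k(scores, 2), c("2", "9"))
  expect_warning(all_nodes <- top_k(scores, 10), "exceeds")
  expect_length(all_nodes, 4)
  expect_error(top_k(scores, 0), "at least 1")
})

test_that("vertex-transitive graphs get equal scores under every measure", {
  for (g in list(generate_graph("complete", 6), generate_graph("cycle", 7))) {
    for (f in list(function(x) cdp(x), degree_centrality,
                   closeness_centrality, betweenness_centrality,
                   function(x) pagerank(x), function(x) cna_ge(x))) {
      sc <- f(g)$scores
      expect_lt(diff(range(sc)), 1e-9)
    }
  }
})
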
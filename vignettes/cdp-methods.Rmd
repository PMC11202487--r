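---
title: "Centrality degree paths: model, validation design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Centrality degree paths: model, validation design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdpath)
```

## The measure

All analyses operate on undirected simple graphs: directed inputs are
symmetrized, self-loops and duplicate edges dropped (with warnings), and
node labels are kept verbatim — integer-looking labels are never
renumbered, so results can be matched back to the source files.

The centrality-degree-paths score of a node $x$ is

$$\mathrm{CDP}(x) = \frac{\deg(x)^2}{P(x,\, l \le d)},$$

where $\deg(x)$ is the **raw** degree (not the degree divided by $N-1$;
the worked example below only reproduces with the raw form) and
$P(x, l \le d)$ counts the simple paths — vertex sequences without
repeats — that start at $x$, end at any other node, and use between 1
and $d$ edges. Each distinct sequence counts once and is counted from
its own start node only; the reverse sequence belongs to the other
endpoint. The length-0 path $x$ itself is excluded. An isolated node has
$\deg = 0$ and no paths; the quotient $0/0$ is defined as 0, since a
node without contacts has no influence and this keeps every score
finite.

The intuition: squaring the degree favours hubs, while the path-count
denominator measures how much *distinct* territory those connections
open up. Two neighbours that are themselves interconnected generate more
bounded paths than two neighbours leading into separate branches, so a
node whose neighbourhood fans out non-redundantly is rewarded relative
to a raw hub.

### The path bound $l$

`l = 2` is the default operating point: the denominator then depends
only on the immediate and second neighbourhoods and has the closed form
$P(x, 2) = \sum_{y \in N(x)} \deg(y)$ (each neighbour $y$ contributes
the edge to $y$ plus its $\deg(y) - 1$ onward continuations), which
`count_all_sources()` exploits. Larger bounds probe deeper structure at
exponentially growing cost: the DFS workload scales roughly with
$|E| \cdot \Delta^{\,l-1}$ for maximum degree $\Delta$. Rather than
silently hanging on large dense graphs, the counters emit a warning when
that estimate exceeds `getOption("cdpath.path_budget", 1e9)`. `cmd_sweep_l()`
exposes the $l$-sweep (default 2–4) so users can check how sensitive
their ranking is; on the small benchmark graphs the CDP ranking is
typically stable between $l = 2$ and $l = 4$, and we make no universal
claim about an optimal $l$.

### The worked example

`example_network()` is a 12-node, 14-edge graph built as a
constraint-verified surrogate: its degree sequence
`3 2 3 2 4 1 2 3 1 2 3 2` and neighbour-degree sums
`7 6 5 7 9 3 6 6 3 7 8 7` are asserted at construction time. For
$l = 2$ those two vectors determine every CDP score, so *any* graph
satisfying both constraints yields the same score table; the shipped
edge list is one such graph. Node 3 (degree 3, path count 5) scores
1.8 and outranks node 5 (degree 4, path count 9, score 1.78) — the
canonical illustration that position can beat raw connectivity. Scores
quoted at two decimals in documentation are **truncated**, not rounded
(9/7 = 1.2857 is quoted as 1.28, 9/8 = 1.125 as 1.12); the API always
returns full precision and only the reporting layer truncates.

## Baseline centralities

* **Degree** — raw count, or normalized by $N-1$ on request.
* **Closeness** — $(N-1)/\sum_j \mathrm{dist}(v, j)$ with BFS geodesics.
  The classical form is only defined on connected graphs; by default we
  apply the Wasserman–Faust per-component scaling
  $\frac{r-1}{N-1}\cdot\frac{r-1}{\sum \mathrm{dist}}$ ($r$ = nodes
  reachable from $v$), which reduces to the classical value when the
  graph is connected and degrades gracefully otherwise. A `strict`
  mode errors on disconnected input instead.
* **Betweenness** — Freeman's unnormalized form over unordered pairs,
  endpoints never counted as interior; computed with Brandes'
  algorithm via igraph and cross-checked in the tests against an
  independent geodesic-counting dynamic program.
* **PageRank** — the per-node fixed point
  $PR(v) = (1-\alpha) + \alpha \sum_{u \sim v} PR(u)/\deg(u)$, iterated
  from the all-ones vector until the maximum per-node change is below
  `tol` (default $10^{-10}$, cap 1000 iterations, non-convergence is an
  error carrying the residual). In this form scores average 1 and sum
  to $N$; it equals the usual unit-sum PageRank multiplied by $N$, and
  the tests verify agreement with igraph's independent implementation.
  Damping defaults to the conventional 0.85.
* **cna_ge** — attribute-weighted degree
  $\deg(v)(\alpha\,e_v + \beta \sum_{j\sim v} e_j)$, designed for
  biological networks where $e$ is a gene-expression level. Weights
  default to $\alpha = \beta = 0.5$ and the attribute to all-ones
  (reducing the score to $\deg(\alpha + \beta\deg)$), since no
  principled attribute exists for non-biological graphs; callers supply
  their own table when they have one.

Ranking ties (`top_k()`) are broken by ascending node label, numerically
when all labels are numeric — a documented, deterministic rule so that
every exported table is byte-reproducible.

## Spreading validation

A centrality is validated by how well it predicts spreading power.
`spreading_efficiency()` runs a synchronous discrete-time stochastic SIR
process: starting from a single infected seed, at every step each
infected node attempts to infect each susceptible neighbour
independently with probability $\beta$, then the nodes that began the
step infected recover with probability $\lambda$. With $\lambda = 1$
(the default) a node is infectious for exactly one step. A run ends when
no infected nodes remain; the score of a run is the number of nodes ever
infected (= recovered + infected at absorption; with $\lambda = 1$
simply the recovered count). Each node is used as seed for `runs`
(default 50) independent runs and the counts are averaged.

Implementation notes:

* The per-step infection of a susceptible node with $k$ infected
  neighbours is drawn once with probability $1 - (1-\beta)^k$ —
  distributionally identical to $k$ independent attempts, and vectorized
  over the node set via a sparse adjacency product.
* Reproducibility: every (seed node, run) pair derives its own 31-bit
  seed from the root `rng_seed`, so results are bit-identical across
  reruns and independent of evaluation order.
* Degenerate regimes are exact anchors used by the tests: $\beta = 0$
  gives efficiency 1 everywhere; $\beta = 1, \lambda = 1$ on a connected
  graph sweeps the whole graph deterministically (efficiency $N$).
  Conservation $|S|+|I|+|R| = N$ can be asserted at every step with
  `check_conservation = TRUE`.
* `max_steps` (default 10000) is a safety cap only: with $\lambda > 0$
  absorption is almost sure, and with $\lambda = 1$ it occurs within
  $N$ steps.
* `suggest_beta()` returns the mean-field epidemic threshold
  $\langle k\rangle / (\langle k^2\rangle - \langle k\rangle)$ as a
  conventional reference point for choosing $\beta$; it is a helper, not
  a prescription, and the shipped `sir_beta_defaults.csv` records the
  $\beta$ values conventionally used with the classic benchmark
  networks.

## Agreement statistics

`compare_measures()` reports four statistics per measure against a
reference (another measure, or spreading efficiency):

* **Pearson** and **Spearman** use the $n-1$ convention internally; the
  normalization cancels in the ratio, so the convention is
  inconsequential and documented only for completeness.
* **Kendall tau** defaults to the plain **tau-a**
  $(\text{concordant} - \text{discordant}) / \binom{n}{2}$: ties count
  as neither concordant nor discordant but stay in the denominator.
  Integer-valued inputs (degrees, infection counts) are tie-heavy, so
  tau-a cannot reach 1 even for identical rankings — a property users
  should know; the tie-corrected tau-b is available via `variant = "b"`.
* **Overlap** $|A \cap B| / \min(|A|, |B|)$ of the two top-$k$ sets,
  with $k = 10$ by default for spreading benchmarks and $k = 6$ for
  ranking tables.
* A constant score vector carries no ordering information: all four
  correlation statistics raise a typed error rather than silently
  returning 0. The workflow commands catch that error and flag the cell
  as `NA` (e.g. Kendall tau at $\beta = 0$, or any correlation on a
  vertex-transitive graph where every centrality is constant).

## What the generators emulate — and what they do not

`generate_graph()` produces the structured topologies whose centralities
are known in closed form (complete, star, cycle, path) plus two random
families (Erdős–Rényi `random_uniform`, Barabási–Albert
`preferential_attachment`) that stand in for sparse irregular networks.
The closed-form cases anchor the analytic tests: CDP is exactly 1 on
every vertex-transitive graph tested, a star hub with $n$ leaves scores
$n$ and each leaf $1/n$, star-hub betweenness is $\binom{n}{2}$, and
PageRank is identically 1 on regular graphs. The random families
exercise the path counter against independent enumeration oracles
(200 seeded graphs, $n \le 40$, $l \in 1..4$, with mean degrees chosen
between 4 and 8 so the enumeration stays exhaustive).

Synthetic graphs of this size do not exhibit the heavy-tailed degree
distributions, community structure or degree correlations of large
real networks, and the bundled karate club (34 nodes) is the only real
network shipped. Passing tests therefore certify the *correctness* of
the implementations and the qualitative behaviour of the measure — not
that CDP outperforms any other centrality on a given real dataset. On
the karate network the test suite checks one robust qualitative
pattern: CDP's Pearson agreement with degree and PageRank exceeds its
agreement with closeness, reflecting that CDP is built from local
degree information while closeness is a long-range distance measure.

The SIR property checks run at Monte-Carlo resolution: 500 runs per seed
node on the 12-node example network for the $\beta$-monotonicity sweep,
50–1000 runs elsewhere. These sizes keep the default suite under a
minute while leaving the stochastic assertions (monotone mean outbreak
size in $\beta$, hub-vs-leaf ordering on a star) several standard errors
away from their thresholds.

## Known limitations

* Exact bounded simple-path counting is exponential in $l$; the package
  is designed for the moderate $l$ (2–4) regime where the measure is
  defined, not as a general path-counting engine.
* Weighted, directed, temporal and multigraph analyses are out of
  scope; inputs are coerced to undirected simple graphs.
* The continuous-time (ODE) SIR formulation is intentionally not
  implemented: rankings require per-seed stochastic realizations, which
  the discrete-time network process provides.
* `cna_ge` on networks without a meaningful node attribute defaults to
  all-ones, which collapses it to a monotone function of degree; its
  behaviour with real expression data depends entirely on that data's
  quality.
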
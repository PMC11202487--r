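check_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least 2 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
}

#' Pearson correlation
#'
#' Sample covariance over the product of sample standard deviations
#' (the `n - 1` convention throughout; the normalization cancels in the
#' ratio). A constant input makes the statistic undefined and raises an
#' error rather than silently returning 0 (the same policy applies to
#' [spearman_cor()] and [kendall_tau()]: a constant carries no ordering
#' information).
#'
#' @param x,y Paired numeric vectors of equal length (at least 2).
#' @return Correlation in `[-1, 1]`.
#' @examples
#' pearson_cor(c(1, 2, 3), c(1, 3, 2))   # 0.5
#' @export
pearson_cor <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_numeric("pearson correlation undefined for constant input")
  as.numeric(cor(x, y, method = "pearson"))
}

#' Spearman rank correlation
#'
#' Pearson correlation applied to ranks; ties receive average ranks.
#'
#' @inheritParams pearson_cor
#' @return Correlation in `[-1, 1]`.
#' @examples
#' spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))   # 0.8
#' @export
spearman_cor <- function(x, y) {
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_numeric("spearman correlation undefined for constant input")
  as.numeric(cor(x, y, method = "spearman"))
}

#' Kendall rank correlation
#'
#' Variant `"a"` (the default) is the plain form
#' `(concordant - discordant) / (n (n - 1) / 2)`: tied pairs count as
#' neither concordant nor discordant but still appear in the
#' denominator, so tie-heavy data cannot reach 1. Variant `"b"` applies
#' the usual tie-corrected denominator
#' `sqrt((n0 - t_x) (n0 - t_y))`.
#'
#' @inheritParams pearson_cor
#' @param variant `"a"` (plain denominator) or `"b"` (tie-corrected).
#' @return Correlation in `[-1, 1]`.
#' @examples
#' kendall_tau(c(1, 2, 3), c(1, 3, 2))   # 1/3
#' @export
kendall_tau <- function(x, y, variant = c("a", "b")) {
  variant <- match.arg(variant)
  check_paired(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_numeric("kendall tau undefined for constant input")
  n <- length(x)
  # Signs of all pairwise differences; concordant pairs have equal
  # nonzero signs, discordant opposite signs.
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  prod_sign <- dx[up] * dy[up]
  concordant <- sum(prod_sign > 0)
  discordant <- sum(prod_sign < 0)
  n0 <- n * (n - 1) / 2
  if (variant == "a") {
    (concordant - discordant) / n0
  } else {
    tx <- sum(dx[up] == 0)
    ty <- sum(dy[up] == 0)
    denom <- sqrt((n0 - tx) * (n0 - ty))
    if (denom == 0)
      stop_numeric("kendall tau-b undefined: all pairs tied")
    (concordant - discordant) / denom
  }
}

#' Overlap coefficient of two node sets
#'
#' `|A intersect B| / min(|A|, |B|)`, typically applied to the top-k
#' node sets of two rankings.
#'
#' @param a,b Non-empty vectors treated as sets (duplicates ignored).
#' @return Overlap in `[0, 1]`.
#' @examples
#' overlap_coefficient(c(1, 2, 3), c(2, 3, 4, 5))   # 2/3
#' @export
overlap_coefficient <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 || length(b) == 0)
    stop("overlap coefficient undefined for empty sets")
  length(intersect(a, b)) / min(length(a), length(b))
}

reference_scores <- function(reference) {
  if (inherits(reference, "centrality_result")) {
    list(name = reference$measure, scores = reference$scores)
  } else if (inherits(reference, "spread_result")) {
    list(name = "spreading_efficiency", scores = reference$efficiency)
  } else if (is.numeric(reference) && !is.null(names(reference))) {
    list(name = "reference", scores = reference)
  } else {
    stop("reference must be a centrality_result, spread_result, or named vector")
  }
}

#' Compare centrality measures against a reference ranking
#'
#' For each measure, computes Pearson, Spearman and Kendall (tau-a)
#' agreement with the reference scores over all nodes, plus the overlap
#' coefficient of the two top-`k` node sets (ties broken as in
#' [top_k()]). The reference is typically a [spreading_efficiency()]
#' result (ground truth) or another centrality.
#'
#' @param results A `centrality_result` or list of them.
#' @param reference A `centrality_result`, `spread_result`, or named
#'   numeric vector on the same node set.
#' @param k Top-k size for the overlap coefficient; default 10.
#' @param kendall_variant Passed to [kendall_tau()].
#' @return A data frame with one row per measure: `measure`, `pearson`,
#'   `spearman`, `kendall`, `overlap_at_k`, `k`, `n`.
#' @export
compare_measures <- function(results, reference, k = 10,
                             kendall_variant = "a") {
  if (inherits(results, "centrality_result")) results <- list(results)
  stopifnot(length(results) > 0,
            all(vapply(results, inherits, logical(1), "centrality_result")))
  ref <- reference_scores(reference)
  nodes <- names(ref$scores)
  for (res in results) {
    extra <- setdiff(names(res$scores), nodes)
    missing <- setdiff(nodes, names(res$scores))
    if (length(extra) > 0 || length(missing) > 0)
      stop(sprintf("node set mismatch for '%s': extra {%s}, missing {%s}",
                   res$measure, paste(extra, collapse = ","),
                   paste(missing, collapse = ",")))
  }
  k_eff <- min(k, length(nodes))
  ref_top <- top_k(ref$scores, k_eff)
  rows <- lapply(results, function(res) {
    s <- res$scores[nodes]
    data.frame(measure = res$measure,
               pearson = pearson_cor(s, ref$scores),
               spearman = spearman_cor(s, ref$scores),
               kendall = kendall_tau(s, ref$scores, variant = kendall_variant),
               overlap_at_k = overlap_coefficient(top_k(s, k_eff), ref_top),
               k = k_eff,
               n = length(nodes),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference") <- ref$name
  out
}
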
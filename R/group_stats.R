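#' @title Two-group nonparametric comparisons
#' @description Rank-sum (Mann-Whitney/Wilcoxon) comparison of nodal
#'   metrics between group graphs, Benjamini-Hochberg FDR adjustment, and
#'   the equal-probability chi-square test on admitted-triangle counts.
#'   Nodal comparisons treat one observation per node of the group matrix,
#'   a descriptive (not subject-level inferential) convention.
#' @name group_stats
NULL

#' Two-sided rank-sum test with normal approximation
#'
#' Wilcoxon rank-sum (Mann-Whitney) test for two independent samples,
#' using the normal approximation with tie correction and no continuity
#' correction, returning the standardized `Z` alongside the p-value.
#'
#' @param x,y Numeric samples (nonempty).
#' @return List with `z`, `p`, and the rank-sum statistic `w` (Mann-Whitney
#'   U of `x`). When every value is tied across both samples the test is
#'   degenerate: `z = 0`, `p = 1`.
#' @export
ranksum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be nonempty")
  if (anyNA(x) || anyNA(y)) stop("samples must not contain NA")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U
  mu <- n1 * n2 / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties)
  sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  if (sigma2 <= 0)  # all observations identical
    return(list(z = 0, p = 1, w = w))
  z <- (w - mu) / sqrt(sigma2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), w = w)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone and capped at 1.
#'
#' @param pvalues Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, never below the raw values.
#' @export
bh_fdr <- function(pvalues) {
  pvalues <- as.numeric(pvalues)
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Chi-square test for given (equal) probabilities
#'
#' Goodness-of-fit test of observed category counts against equal expected
#' counts; used to compare the number of admitted triangles between
#' groups.
#'
#' @param counts Nonnegative integer counts, at least two categories.
#' @return List with `chisq`, `df` (`k - 1`) and `p`. All-zero counts are
#'   degenerate: `chisq = 0`, `p = 1`.
#' @export
chisq_equal_prob <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2L) stop("need at least two categories")
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  df <- length(counts) - 1L
  if (sum(counts) == 0)
    return(list(chisq = 0, df = df, p = 1))
  ct <- suppressWarnings(stats::chisq.test(counts))
  list(chisq = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' Compare nodal metrics between two group graphs
#'
#' Runs the rank-sum test on each nodal metric (degree, clustering
#' coefficient, local efficiency), one observation per node, between two
#' binary group graphs over the same node set. Raw p-values are returned;
#' FDR adjustment across the comparison family is applied by the caller
#' (see [run_pipeline()]), since the family spans all metrics and scopes
#' of a run.
#'
#' @param g_a,g_b [fc_graph()] objects with identical labels (e.g.
#'   controls and patients).
#' @param scope Name recorded on the rows.
#' @return Data frame with columns `scope, metric, z, p, n_nodes`.
#' @export
compare_nodal_metrics <- function(g_a, g_b, scope = "whole_brain") {
  stopifnot(inherits(g_a, "fc_graph"), inherits(g_b, "fc_graph"))
  if (!identical(rownames(g_a), rownames(g_b)))
    stop("group graphs have mismatched node labels")
  panels <- list(
    degree = list(as.numeric(node_degree(g_a)),
                  as.numeric(node_degree(g_b))),
    clustering = list(clustering_coefficient(g_a),
                      clustering_coefficient(g_b)),
    local_efficiency = list(local_efficiency(g_a), local_efficiency(g_b))
  )
  rows <- lapply(names(panels), function(m) {
    t <- ranksum_test(panels[[m]][[1L]], panels[[m]][[2L]])
    data.frame(scope = scope, metric = m, z = t$z, p = t$p,
               n_nodes = nrow(g_a))
  })
  do.call(rbind, rows)
}
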
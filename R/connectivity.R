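#' @title Connectivity matrices
#' @description Constructors and operations on region-by-region functional
#'   connectivity matrices. Matrices live either in correlation space
#'   (`space = "r"`, entries in `[0, 1]` after zeroing anti-correlations)
#'   or Fisher z space (`space = "z"`). All operations preserve symmetry
#'   and the zero diagonal.
#' @name connectivity
NULL

# clip applied before arctanh so r == 1 (identical series) stays finite
.R_CLIP <- 1 - 1e-12

#' Construct a connectivity matrix
#'
#' @param values Symmetric numeric matrix with zero diagonal, one
#'   row/column per atlas region.
#' @param labels Character vector of region labels in atlas order; taken
#'   from `dimnames(values)` when omitted.
#' @param space `"r"` (correlation) or `"z"` (Fisher-transformed).
#' @return The matrix with class `fc_matrix` and a `space` attribute.
#' @export
fc_matrix <- function(values, labels = NULL, space = c("r", "z")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (nrow(values) != ncol(values))
    stop("connectivity matrix must be square")
  if (any(!is.finite(values)))
    stop("connectivity matrix contains non-finite entries")
  if (max(abs(values - t(values))) > 1e-8)
    stop("connectivity matrix must be symmetric")
  if (any(diag(values) != 0))
    stop("connectivity matrix must have a zero diagonal")
  if (space == "r" && (min(values) < 0 || max(values) > 1))
    stop("r-space entries must lie in [0, 1]")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(values)))
  if (length(labels) != nrow(values))
    stop("labels length must match matrix dimension")
  dimnames(values) <- list(labels, labels)
  structure(values, space = space, class = c("fc_matrix", "matrix", "array"))
}

#' @export
print.fc_matrix <- function(x, ...) {
  cat(sprintf("<fc_matrix> %d x %d, space = %s\n",
              nrow(x), ncol(x), attr(x, "space")))
  invisible(x)
}

fc_space <- function(C) attr(C, "space")

#' Pearson full-correlation matrix from regional time series
#'
#' Computes pairwise Pearson correlations between the mean time courses of
#' all regions, then zeroes the diagonal (autocorrelations) and all
#' negative coefficients (anti-correlations), whose interpretation at rest
#' is contested and whose magnitudes are typically negligible.
#'
#' @param ts Numeric matrix, regions as rows (atlas order) and timepoints
#'   as columns; at least 3 timepoints; no constant row.
#' @param labels Optional region labels; defaults to rownames.
#' @return An [fc_matrix()] in r space.
#' @export
pearson_matrix <- function(ts, labels = NULL) {
  if (!is.matrix(ts) || !is.numeric(ts))
    stop("time series must be a numeric matrix (regions x timepoints)")
  if (ncol(ts) < 3L) stop("need at least 3 timepoints")
  if (any(!is.finite(ts))) stop("time series contains non-finite values")
  sds <- apply(ts, 1L, stats::sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    nm <- if (!is.null(rownames(ts))) rownames(ts)[bad] else bad
    stop("constant (zero-variance) time series for region(s): ",
         paste(nm, collapse = ", "))
  }
  r <- stats::cor(t(ts))
  diag(r) <- 0
  r[r < 0] <- 0
  r <- pmin(r, 1)
  fc_matrix(r, labels = labels %||% rownames(ts), space = "r")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fisher r-to-z transform (and inverse)
#'
#' Entrywise `atanh` of an r-space matrix; zeros map to zeros. Entries at
#' or above `1 - 1e-12` are clipped to that value before transforming so
#' perfectly correlated pairs stay finite.
#'
#' @param C An [fc_matrix()] in r space (for `fisher_z`) or z space (for
#'   `inverse_fisher`).
#' @return An [fc_matrix()] in the other space.
#' @export
fisher_z <- function(C) {
  stopifnot(inherits(C, "fc_matrix"))
  if (fc_space(C) != "r") stop("fisher_z expects an r-space matrix")
  v <- pmin(unclass(C), .R_CLIP)
  fc_matrix(atanh(v), labels = rownames(C), space = "z")
}

#' @rdname fisher_z
#' @export
inverse_fisher <- function(C) {
  stopifnot(inherits(C, "fc_matrix"))
  if (fc_space(C) != "z") stop("inverse_fisher expects a z-space matrix")
  fc_matrix(tanh(unclass(C)), labels = rownames(C), space = "r")
}

#' Group-average connectivity matrix
#'
#' Averages subject correlation matrices entrywise in Fisher z space and
#' back-transforms the mean to r space. Cells that are zero in every
#' subject stay exactly zero.
#'
#' @param subject_matrices List of r-space [fc_matrix()] objects with
#'   identical labels.
#' @return Group [fc_matrix()] in r space.
#' @export
group_mean <- function(subject_matrices) {
  if (!is.list(subject_matrices) || length(subject_matrices) == 0L)
    stop("need at least one subject matrix")
  ref <- subject_matrices[[1L]]
  stopifnot(inherits(ref, "fc_matrix"))
  for (m in subject_matrices) {
    if (!inherits(m, "fc_matrix") || fc_space(m) != "r")
      stop("all subject matrices must be r-space fc_matrix objects")
    if (!identical(rownames(m), rownames(ref)))
      stop("subject matrices have mismatched region labels")
  }
  zs <- lapply(subject_matrices, function(m) unclass(fisher_z(m)))
  zbar <- Reduce(`+`, zs) / length(zs)
  fc_matrix(tanh(zbar), labels = rownames(ref), space = "r")
}

#' Apply an absolute threshold
#'
#' Keeps entries strictly greater than `thr` (an entry exactly at the
#' threshold is removed), either retaining the correlation weights
#' (`mode = "weighted"`) or binarizing them (`mode = "binary"`).
#'
#' @param C An r-space [fc_matrix()].
#' @param thr Threshold in `[0, 1]`.
#' @param mode `"weighted"` or `"binary"`.
#' @return An [fc_matrix()] (weighted) or [fc_graph()] (binary).
#' @export
apply_threshold <- function(C, thr, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  stopifnot(inherits(C, "fc_matrix"))
  if (fc_space(C) != "r") stop("threshold is defined on the r scale")
  if (!is.numeric(thr) || length(thr) != 1L || is.na(thr) ||
      thr < 0 || thr > 1)
    stop("threshold must be a single value in [0, 1]")
  keep <- unclass(C) > thr
  if (mode == "weighted") {
    v <- unclass(C)
    v[!keep] <- 0
    fc_matrix(v, labels = rownames(C), space = "r")
  } else {
    fc_graph(keep * 1, labels = rownames(C))
  }
}

#' Construct a binary undirected graph
#'
#' @param adjacency Symmetric 0/1 numeric matrix with zero diagonal.
#' @param labels Node labels; defaults to rownames.
#' @return The adjacency matrix with class `fc_graph`.
#' @export
fc_graph <- function(adjacency, labels = NULL) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop("adjacency must be a numeric matrix")
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1)))
    stop("adjacency entries must be 0 or 1")
  if (max(abs(adjacency - t(adjacency))) > 0)
    stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  if (is.null(labels)) labels <- rownames(adjacency)
  if (is.null(labels)) labels <- paste0("ROI", seq_len(nrow(adjacency)))
  dimnames(adjacency) <- list(labels, labels)
  structure(adjacency, class = c("fc_graph", "matrix", "array"))
}

#' @export
print.fc_graph <- function(x, ...) {
  cat(sprintf("<fc_graph> %d nodes, %d edges\n",
              nrow(x), sum(unclass(x)) / 2))
  invisible(x)
}

#' Count above-threshold connections (directed convention)
#'
#' Number of nonzero off-diagonal cells of the adjacency matrix, i.e.
#' twice the undirected edge count — the convention used when reporting
#' "above threshold connections" per network.
#'
#' @param G An [fc_graph()].
#' @return Integer count.
#' @export
connection_count <- function(G) {
  stopifnot(inherits(G, "fc_graph"))
  as.integer(sum(unclass(G)))
}

#' Network density across an absolute-threshold sweep
#'
#' For each threshold, the proportion of possible undirected edges whose
#' correlation exceeds it (strictly), within the whole matrix or a node
#' subset. Density is non-increasing in the threshold and the surviving
#' edge sets are nested across the sweep.
#'
#' @param C An r-space [fc_matrix()].
#' @param thresholds Numeric vector of thresholds in `[0, 1]`; default the
#'   sensitivity range 0.40 to 0.50 in steps of 0.01.
#' @param indices Optional 1-based node indices restricting the scope.
#' @return Data frame with columns `threshold`, `n_edges`, `density`.
#' @export
density_sweep <- function(C, thresholds = seq(0.40, 0.50, by = 0.01),
                          indices = NULL) {
  stopifnot(inherits(C, "fc_matrix"))
  if (fc_space(C) != "r") stop("density sweep is defined on the r scale")
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0, 1]")
  v <- unclass(C)
  if (!is.null(indices)) v <- v[indices, indices, drop = FALSE]
  n <- nrow(v)
  if (n < 2L) stop("need at least 2 nodes for a density")
  upper <- v[upper.tri(v)]
  n_pairs <- n * (n - 1) / 2
  edges <- vapply(thresholds, function(t) sum(upper > t), numeric(1))
  data.frame(threshold = thresholds,
             n_edges = as.integer(edges),
             density = edges / n_pairs)
}
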
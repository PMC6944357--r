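#' @title Binary graph metric panel
#' @description The five metrics extracted from thresholded, binarized
#'   connectivity matrices: node degree, nodal clustering coefficient,
#'   nodal local efficiency, characteristic path length and global
#'   efficiency. Distances are unweighted shortest-path (breadth-first)
#'   distances. Disconnected graphs are handled by averaging path lengths
#'   over reachable pairs only and by the convention `1/Inf = 0` for
#'   efficiencies.
#' @name graph_metrics_panel
NULL

.as_adjacency <- function(G) {
  stopifnot(inherits(G, "fc_graph"))
  unclass(G)
}

.shortest_distances <- function(A) {
  if (nrow(A) == 0L) return(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::distances(g)  # BFS on unweighted graphs; Inf if unreachable
}

#' Node degree
#'
#' Number of edges connecting each node with all the others.
#'
#' @param G An [fc_graph()].
#' @return Named integer vector, one entry per node.
#' @export
node_degree <- function(G) {
  A <- .as_adjacency(G)
  d <- as.integer(rowSums(A))
  names(d) <- rownames(A)
  d
}

#' Nodal clustering coefficient
#'
#' Normalized number of pairs of each node's neighbors that are connected
#' with each other: `C_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` is the
#' number of triangles through node i; 0 for nodes with fewer than two
#' neighbors.
#'
#' @param G An [fc_graph()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
clustering_coefficient <- function(G) {
  A <- .as_adjacency(G)
  k <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  cc <- ifelse(k < 2, 0, 2 * tri / (k * (k - 1)))
  names(cc) <- rownames(A)
  cc
}

.efficiency_from_dist <- function(D) {
  n <- nrow(D)
  if (n < 2L) return(0)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' Mean of inverse shortest-path distances over all ordered distinct node
#' pairs, with unreachable pairs contributing 0. Equals 1 on a complete
#' graph and 0 on an edgeless one.
#'
#' @param G An [fc_graph()].
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(G) {
  A <- .as_adjacency(G)
  .efficiency_from_dist(.shortest_distances(A))
}

#' Nodal local efficiency
#'
#' For each node, the global efficiency of the subgraph induced by its
#' neighbors — an index of integration of a node with its immediate
#' neighborhood; 0 for nodes with fewer than two neighbors.
#'
#' @param G An [fc_graph()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
local_efficiency <- function(G) {
  A <- .as_adjacency(G)
  n <- nrow(A)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2L) next
    le[i] <- .efficiency_from_dist(
      .shortest_distances(A[nb, nb, drop = FALSE]))
  }
  names(le) <- rownames(A)
  le
}

#' Characteristic path length
#'
#' Average shortest-path distance over all reachable ordered distinct node
#' pairs. Unreachable pairs are excluded from the average and their count
#' reported; an edgeless graph has no defined path length.
#'
#' @param G An [fc_graph()].
#' @return A number `>= 1`, with attributes `n_unreachable_pairs` (ordered
#'   pairs excluded) and `n_pairs_used`; `NA` (with attributes) when the
#'   graph has no edges.
#' @export
characteristic_path_length <- function(G) {
  A <- .as_adjacency(G)
  D <- .shortest_distances(A)
  off <- D[row(D) != col(D)]
  reach <- off[is.finite(off)]
  cpl <- if (length(reach) == 0L) NA_real_ else mean(reach)
  structure(cpl,
            n_unreachable_pairs = sum(!is.finite(off)),
            n_pairs_used = length(reach))
}

#' Summarise a nodal metric
#'
#' Mean and sample (n-1) standard deviation of a nodal metric. By default
#' isolated nodes (degree 0) are excluded before averaging, matching the
#' convention under which the reported group means of sparse networks are
#' reproducible; set `include_isolated = TRUE` to average over all nodes.
#'
#' @param values Numeric vector, one value per node.
#' @param degrees Integer vector of node degrees, same length.
#' @param include_isolated Keep degree-0 nodes in the average.
#' @return List with `mean`, `sd` (NA when fewer than 2 nodes used) and
#'   `n_used`; `mean` is `NA` with `n_used = 0` when no node qualifies.
#' @export
nodal_summary <- function(values, degrees, include_isolated = FALSE) {
  if (length(values) != length(degrees))
    stop("values and degrees must have the same length")
  keep <- if (include_isolated) rep(TRUE, length(values)) else degrees > 0
  v <- values[keep]
  if (length(v) == 0L)
    return(list(mean = NA_real_, sd = NA_real_, n_used = 0L))
  list(mean = mean(v),
       sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
       n_used = length(v))
}

#' Full metric panel for a binary graph
#'
#' Computes all five metrics plus nodal summaries in one call.
#'
#' @param G An [fc_graph()].
#' @param include_isolated Passed to [nodal_summary()].
#' @return A list of class `graph_metrics` with per-node vectors
#'   (`degree`, `clustering`, `local_efficiency`), the two global scalars,
#'   and a `summary` data frame (one row per nodal metric: mean, sd,
#'   n_used).
#' @export
graph_metrics <- function(G, include_isolated = FALSE) {
  deg <- node_degree(G)
  cc <- clustering_coefficient(G)
  le <- local_efficiency(G)
  cpl <- characteristic_path_length(G)
  ge <- global_efficiency(G)
  rows <- lapply(list(degree = as.numeric(deg), clustering = cc,
                      local_efficiency = le),
                 nodal_summary, degrees = deg,
                 include_isolated = include_isolated)
  summary <- data.frame(
    metric = names(rows),
    mean = vapply(rows, `[[`, numeric(1), "mean"),
    sd = vapply(rows, `[[`, numeric(1), "sd"),
    n_used = vapply(rows, `[[`, integer(1), "n_used"),
    row.names = NULL
  )
  structure(list(
    degree = deg,
    clustering = cc,
    local_efficiency = le,
    characteristic_path_length = as.numeric(cpl),
    cpl_unreachable_pairs = attr(cpl, "n_unreachable_pairs"),
    global_efficiency = ge,
    summary = summary,
    include_isolated = include_isolated,
    computable = connection_count(G) > 0L
  ), class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  if (!x$computable) {
    cat("<graph_metrics> not computable: graph has no edges\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<graph_metrics> %d nodes | CPL %.4g | global eff %.4g\n",
    length(x$degree), x$characteristic_path_length, x$global_efficiency))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
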
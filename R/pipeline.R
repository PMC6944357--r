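#' @title Full analysis pipeline
#' @description Orchestrates the whole analysis — group correlation
#'   matrices, absolute thresholding, density sweep, graph-metric panel,
#'   triangle segregation and group comparisons — per scope (each
#'   resting-state network, the combined RSN node set, and the whole
#'   brain), from a config describing the inputs, and writes every table
#'   as CSV with a provenance header.
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' @param cohort_dir Directory holding subject time-series CSVs and a
#'   `manifest.csv` (as written by [write_cohort()]). Alternatively pass
#'   an in-memory `cohort` via `cohort`.
#' @param cohort Optional in-memory cohort (overrides `cohort_dir`).
#' @param atlas_path Optional atlas CSV; default the bundled AAL-90 table.
#' @param networks_path Optional YAML/JSON network file; default bundled.
#' @param main_threshold Absolute correlation threshold for the reported
#'   graphs (default 0.5); must lie within the sweep range.
#' @param sweep Thresholds for the density sensitivity sweep (default
#'   0.40-0.50 in steps of 0.01).
#' @param triangle_side Side of the equilateral triangle defining the
#'   area admission threshold (default 0.6).
#' @param include_isolated Include degree-0 nodes in nodal metric means.
#' @param output_dir Where tables are written.
#' @param seed Recorded in provenance headers (the analysis itself is
#'   deterministic).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort_dir = NULL, cohort = NULL,
                            atlas_path = NULL, networks_path = NULL,
                            main_threshold = 0.5,
                            sweep = seq(0.40, 0.50, by = 0.01),
                            triangle_side = 0.6,
                            include_isolated = FALSE,
                            output_dir = "results",
                            seed = NULL) {
  if (is.null(cohort_dir) && is.null(cohort))
    stop("provide cohort_dir or an in-memory cohort")
  if (main_threshold < min(sweep) || main_threshold > max(sweep))
    stop("main_threshold must lie within the sweep range [",
         min(sweep), ", ", max(sweep), "]")
  if (any(sweep < 0 | sweep > 1)) stop("sweep thresholds must lie in [0, 1]")
  structure(list(
    cohort_dir = cohort_dir, cohort = cohort,
    atlas_path = atlas_path, networks_path = networks_path,
    main_threshold = main_threshold, sweep = sweep,
    triangle_side = triangle_side,
    include_isolated = include_isolated,
    output_dir = output_dir, seed = seed
  ), class = "pipeline_config")
}

.read_cohort_dir <- function(dir) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"))
  need <- c("subject_id", "group", "file")
  if (!all(need %in% names(manifest)))
    stop("manifest.csv must have columns ", paste(need, collapse = ", "))
  groups <- list(controls = list(), patients = list())
  for (i in seq_len(nrow(manifest))) {
    grp <- paste0(manifest$group[i], "s")
    if (!grp %in% names(groups))
      stop("unknown group '", manifest$group[i], "' in manifest row ", i)
    groups[[grp]][[manifest$subject_id[i]]] <-
      read_timeseries(file.path(dir, manifest$file[i]))
  }
  groups
}

#' Group-level analysis over precomputed group matrices
#'
#' The computational core of the pipeline: given one r-space group matrix
#' per group, computes for every scope the connection count, density
#' sweep, metric panel and triangle estimators, plus between-group
#' rank-sum comparisons (FDR-adjusted across the whole metric x scope
#' family) and the equal-probability chi-square on triangle counts.
#'
#' @param group_matrices Named list of r-space [fc_matrix()] objects
#'   (typically `control` and `patient`), identical labels.
#' @param atlas An `atlas_table` matching the matrix row order.
#' @param networks Named list of [network_definition()]s.
#' @param main_threshold,sweep,triangle_side,include_isolated See
#'   [pipeline_config()].
#' @return A list of class `fc_report`: `scopes` (per scope, per group:
#'   graph, metrics, triangle set), and tables `connection_counts`,
#'   `density`, `metrics`, `triangles`, `comparisons`,
#'   `triangle_count_tests`.
#' @export
analyze_group_matrices <- function(group_matrices, atlas,
                                   networks = default_networks(),
                                   main_threshold = 0.5,
                                   sweep = seq(0.40, 0.50, by = 0.01),
                                   triangle_side = 0.6,
                                   include_isolated = FALSE) {
  stopifnot(is.list(group_matrices), length(group_matrices) >= 1L,
            !is.null(names(group_matrices)))
  labels <- rownames(group_matrices[[1L]])
  for (m in group_matrices)
    if (!identical(rownames(m), labels))
      stop("group matrices have mismatched labels")
  if (!identical(atlas$label, labels))
    stop("atlas labels do not match matrix labels")

  net_idx <- lapply(networks, function(net)
    resolve_members(atlas, net, one_based = TRUE))
  scopes <- c(net_idx,
              list(RSNs = sort(unique(unlist(net_idx))),
                   whole_brain = seq_along(labels)))
  area_thr <- area_threshold(triangle_side)

  scope_results <- list()
  counts <- density <- metrics <- triangles <- list()
  for (sc in names(scopes)) {
    idx <- scopes[[sc]]
    if (length(idx) < 3L) {
      warning("scope '", sc, "' has fewer than 3 nodes; skipped")
      next
    }
    for (grp in names(group_matrices)) {
      C <- group_matrices[[grp]]
      sub <- fc_matrix(unclass(C)[idx, idx, drop = FALSE],
                       labels = labels[idx], space = "r")
      G <- apply_threshold(sub, main_threshold, mode = "binary")
      mt <- graph_metrics(G, include_isolated = include_isolated)
      tri <- enumerate_triangles(sub, thr = area_thr, scope = sc)
      scope_results[[sc]][[grp]] <-
        list(graph = G, metrics = mt, triangles = tri)

      counts[[length(counts) + 1L]] <- data.frame(
        scope = sc, group = grp,
        connections = connection_count(G))
      dsw <- density_sweep(C, thresholds = sweep, indices = idx)
      density[[length(density) + 1L]] <-
        cbind(scope = sc, group = grp, dsw)
      s <- mt$summary
      metrics[[length(metrics) + 1L]] <- data.frame(
        scope = sc, group = grp, computable = mt$computable,
        clustering_mean = s$mean[s$metric == "clustering"],
        clustering_sd = s$sd[s$metric == "clustering"],
        local_eff_mean = s$mean[s$metric == "local_efficiency"],
        local_eff_sd = s$sd[s$metric == "local_efficiency"],
        path_length = mt$characteristic_path_length,
        global_efficiency = mt$global_efficiency,
        degree_mean = s$mean[s$metric == "degree"],
        degree_sd = s$sd[s$metric == "degree"],
        n_nodes_used = s$n_used[s$metric == "degree"])
      est <- triangle_estimators(tri)
      triangles[[length(triangles) + 1L]] <-
        cbind(group = grp, est)
    }
  }

  comparisons <- tri_tests <- NULL
  if (all(c("control", "patient") %in% names(group_matrices))) {
    comp <- lapply(names(scope_results), function(sc)
      compare_nodal_metrics(scope_results[[sc]]$control$graph,
                            scope_results[[sc]]$patient$graph,
                            scope = sc))
    comparisons <- do.call(rbind, comp)
    comparisons$p_fdr <- bh_fdr(comparisons$p)
    comparisons$fdr_family_size <- nrow(comparisons)

    tri_tests <- do.call(rbind, lapply(names(scope_results), function(sc) {
      n_c <- nrow(scope_results[[sc]]$control$triangles$triangles)
      n_p <- nrow(scope_results[[sc]]$patient$triangles$triangles)
      if (n_c + n_p == 0L)
        return(data.frame(scope = sc, n_control = 0L, n_patient = 0L,
                          chisq = NA_real_, df = 1L, p = NA_real_))
      ct <- chisq_equal_prob(c(n_c, n_p))
      data.frame(scope = sc, n_control = n_c, n_patient = n_p,
                 chisq = ct$chisq, df = ct$df, p = ct$p)
    }))
  }

  structure(list(
    scopes = scope_results,
    connection_counts = do.call(rbind, counts),
    density = do.call(rbind, density),
    metrics = do.call(rbind, metrics),
    triangles = do.call(rbind, triangles),
    comparisons = comparisons,
    triangle_count_tests = tri_tests,
    settings = list(main_threshold = main_threshold, sweep = sweep,
                    triangle_side = triangle_side,
                    area_threshold = area_thr,
                    include_isolated = include_isolated)
  ), class = "fc_report")
}

.provenance_header <- function(config_hash, seed) {
  c(sprintf("# rsfcnet %s",
            as.character(utils::packageVersion("rsfcnet"))),
    sprintf("# config_hash: %s", config_hash),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else seed))
}

.write_table <- function(df, path, header_lines) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full pipeline from a configuration
#'
#' Reads (or takes) the cohort, builds per-subject Pearson matrices and
#' the Fisher-aggregated group matrices, runs [analyze_group_matrices()]
#' over every scope, and writes all result tables under the configured
#' output directory: `connection_counts.csv`, `density_sweep.csv`,
#' `graph_metrics.csv`, `triangle_estimators.csv`,
#' `nodal_comparisons.csv`, `triangle_count_tests.csv`,
#' `group_matrix_<group>.csv` and a `manifest.json`. Re-running with the
#' same inputs and config is deterministic.
#'
#' @param config A [pipeline_config()].
#' @return The `fc_report`, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  atlas <- if (is.null(config$atlas_path)) aal90_atlas()
           else load_atlas(config$atlas_path)
  networks <- default_networks(config$networks_path)

  cohort <- config$cohort
  if (is.null(cohort)) {
    groups <- .read_cohort_dir(config$cohort_dir)
  } else {
    groups <- cohort[c("controls", "patients")]
  }
  group_matrices <- list()
  for (grp in names(groups)) {
    if (length(groups[[grp]]) == 0L) next
    subj <- lapply(groups[[grp]], function(ts) {
      if (!identical(rownames(ts), atlas$label))
        stop("subject time-series rows do not match the atlas order")
      pearson_matrix(ts)
    })
    group_matrices[[sub("s$", "", grp)]] <- group_mean(subj)
  }

  report <- analyze_group_matrices(
    group_matrices, atlas, networks,
    main_threshold = config$main_threshold,
    sweep = config$sweep,
    triangle_side = config$triangle_side,
    include_isolated = config$include_isolated)

  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  # hash covers the analysis settings, not where results land
  cfg_json <- jsonlite::toJSON(
    config[c("atlas_path", "networks_path", "main_threshold", "sweep",
             "triangle_side", "include_isolated")],
    auto_unbox = TRUE, null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  hash <- unname(tools::md5sum(tmp)); unlink(tmp)
  hdr <- .provenance_header(hash, config$seed)

  .write_table(report$connection_counts,
               file.path(out, "connection_counts.csv"), hdr)
  .write_table(report$density, file.path(out, "density_sweep.csv"), hdr)
  .write_table(report$metrics, file.path(out, "graph_metrics.csv"), hdr)
  .write_table(report$triangles,
               file.path(out, "triangle_estimators.csv"), hdr)
  if (!is.null(report$comparisons))
    .write_table(report$comparisons,
                 file.path(out, "nodal_comparisons.csv"), hdr)
  if (!is.null(report$triangle_count_tests))
    .write_table(report$triangle_count_tests,
                 file.path(out, "triangle_count_tests.csv"), hdr)
  for (grp in names(group_matrices)) {
    m <- group_matrices[[grp]]
    .write_table(data.frame(label = rownames(m), unclass(m),
                            check.names = FALSE),
                 file.path(out, paste0("group_matrix_", grp, ".csv")), hdr)
  }
  jsonlite::write_json(
    list(tool = "rsfcnet",
         version = as.character(utils::packageVersion("rsfcnet")),
         config_hash = hash, seed = config$seed,
         settings = report$settings,
         tables = c("connection_counts.csv", "density_sweep.csv",
                    "graph_metrics.csv", "triangle_estimators.csv",
                    "nodal_comparisons.csv", "triangle_count_tests.csv")),
    file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Export BrainNet Viewer node/edge files
#'
#' Writes the whitespace-separated `.node` (x y z color size label, one
#' row per region) and `.edge` (N x N matrix) text files used by external
#' connectome viewers. The `.edge` file round-trips: reading it back with
#' [read_edge_file()] reproduces the matrix exactly.
#'
#' @param atlas An `atlas_table` providing coordinates; only rows whose
#'   labels appear in `G` are exported, in `G`'s order.
#' @param G An [fc_graph()] or [fc_matrix()].
#' @param node_path,edge_path Output file paths.
#' @param node_color Integer color code per node (recycled).
#' @param node_size Node size column; default the node degree (graphs) or
#'   strength (weighted matrices).
#' @return Invisibly, a list with the two paths.
#' @export
export_brainnet <- function(atlas, G, node_path, edge_path,
                            node_color = 1, node_size = NULL) {
  stopifnot(inherits(atlas, "atlas_table"))
  if (!inherits(G, "fc_graph") && !inherits(G, "fc_matrix"))
    stop("G must be an fc_graph or fc_matrix")
  labels <- rownames(G)
  pos <- match(labels, atlas$label)
  if (anyNA(pos))
    stop("graph label(s) missing from the atlas: ",
         paste(labels[is.na(pos)], collapse = ", "))
  v <- unclass(G)
  if (is.null(node_size)) node_size <- rowSums(v)
  node_color <- rep_len(node_color, length(labels))
  node_lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                        format(atlas$x[pos], trim = TRUE),
                        format(atlas$y[pos], trim = TRUE),
                        format(atlas$z[pos], trim = TRUE),
                        format(node_color, trim = TRUE),
                        format(node_size, trim = TRUE),
                        labels)
  writeLines(node_lines, node_path)
  edge_lines <- apply(v, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(edge_lines, edge_path)
  invisible(list(node = node_path, edge = edge_path))
}

#' Read a BrainNet Viewer `.edge` file back into a matrix
#'
#' @param path Whitespace-separated N x N text matrix.
#' @return Numeric matrix.
#' @export
read_edge_file <- function(path) {
  unname(as.matrix(utils::read.table(path, header = FALSE)))
}
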
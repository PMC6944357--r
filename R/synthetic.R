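#' @title Synthetic two-group resting-state cohorts
#' @description Generates control and patient cohorts of regional time
#'   series with block-structured covariance: compound symmetry within
#'   each resting-state network, a common background correlation between
#'   all other pairs, and an attenuated visual-network block in patients.
#'   This emulates the study conditions the pipeline targets — two groups
#'   of 10 subjects, 160 timepoints, controls with stronger within-VN
#'   coupling — so every downstream stage runs without raw imaging data.
#' @name synthetic_cohort
NULL

#' Specify a synthetic cohort
#'
#' Defaults encode the emulated study conditions: 10 controls and 10
#' patients, 160 timepoints per subject, within-network correlation
#' targets of 0.67 (VN — the equilateral side implied by the reported
#' control VN mean triangle area of 0.193, and consistent with a
#' near-complete VN above the 0.5 threshold), 0.48 (DMN), 0.45 (AN) and
#' 0.42 (SN), background correlation 0.2, patient VN attenuation 0.5
#' (the patient VN block target is `0.67 * 0.5 = 0.335`), and additive
#' white measurement noise of sd 0.1 (the stated targets are marginal —
#' the signal covariance is scaled so observed correlations hit them
#' after noise).
#'
#' @param n_controls,n_patients Subjects per group.
#' @param n_timepoints Timepoints per subject.
#' @param atlas An `atlas_table`; default [aal90_atlas()].
#' @param networks Named list of [network_definition()]s; default
#'   [default_networks()].
#' @param within_network_r Named numeric vector of within-network
#'   correlation targets (names must match `networks`), in `[0, 1)`.
#' @param between_network_r Background correlation for all other pairs.
#' @param patient_vn_attenuation Multiplier in `[0, 1]` applied to the VN
#'   block target in the patient group (1 = no group difference).
#' @param vn_name Name of the attenuated network within `networks`.
#' @param noise_sd Additive white-noise standard deviation.
#' @param ar_coefficient Optional AR(1) coefficient in `[0, 1)` for
#'   temporally autocorrelated signals (marginal covariance is preserved);
#'   0 gives i.i.d. samples.
#' @param seed Integer seed; fixed seed gives bit-identical cohorts.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_controls = 10L, n_patients = 10L,
                        n_timepoints = 160L,
                        atlas = aal90_atlas(),
                        networks = default_networks(),
                        within_network_r = c(VN = 0.67, DMN = 0.48,
                                             AN = 0.45, SN = 0.42),
                        between_network_r = 0.2,
                        patient_vn_attenuation = 0.5,
                        vn_name = "VN",
                        noise_sd = 0.1,
                        ar_coefficient = 0,
                        seed = 1L) {
  stopifnot(n_controls >= 1L, n_patients >= 1L, n_timepoints >= 3L)
  if (!all(names(within_network_r) %in% names(networks)))
    stop("within_network_r names must match network names")
  if (any(within_network_r < 0 | within_network_r >= 1))
    stop("within-network correlation targets must lie in [0, 1)")
  if (between_network_r < 0 || between_network_r >= 1)
    stop("between-network correlation must lie in [0, 1)")
  if (patient_vn_attenuation < 0 || patient_vn_attenuation > 1)
    stop("patient_vn_attenuation must lie in [0, 1]")
  if (!vn_name %in% names(networks))
    stop("vn_name '", vn_name, "' is not a defined network")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  if (ar_coefficient < 0 || ar_coefficient >= 1)
    stop("ar_coefficient must lie in [0, 1)")
  structure(list(
    n_controls = as.integer(n_controls),
    n_patients = as.integer(n_patients),
    n_timepoints = as.integer(n_timepoints),
    atlas = atlas, networks = networks,
    within_network_r = within_network_r,
    between_network_r = between_network_r,
    patient_vn_attenuation = patient_vn_attenuation,
    vn_name = vn_name,
    noise_sd = noise_sd,
    ar_coefficient = ar_coefficient,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Group covariance (correlation) matrix of a cohort spec
#'
#' Builds the target marginal correlation matrix for one group: unit
#' diagonal, within-network blocks at the group's target (the VN block
#' multiplied by the attenuation for patients), all other entries at the
#' background level. If the assembled matrix is not positive
#' semidefinite it is repaired by flooring negative eigenvalues at zero
#' and rescaling back to unit diagonal.
#'
#' @param spec A [cohort_spec()].
#' @param group `"control"` or `"patient"`.
#' @return Symmetric correlation matrix (regions x regions, atlas order,
#'   labelled).
#' @export
build_covariance <- function(spec, group = c("control", "patient")) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "cohort_spec"))
  n <- nrow(spec$atlas)
  R <- matrix(spec$between_network_r, n, n)
  for (nm in names(spec$within_network_r)) {
    idx <- resolve_members(spec$atlas, spec$networks[[nm]], one_based = TRUE)
    r <- spec$within_network_r[[nm]]
    if (group == "patient" && nm == spec$vn_name)
      r <- r * spec$patient_vn_attenuation
    R[idx, idx] <- r
  }
  diag(R) <- 1
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 0) {
    vals <- pmax(ev$values, 0)
    R <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    d <- sqrt(diag(R))
    if (any(d == 0))
      stop("correlation targets produce a non-repairable covariance")
    R <- R / tcrossprod(d)
    diag(R) <- 1
    R <- (R + t(R)) / 2
  }
  dimnames(R) <- list(spec$atlas$label, spec$atlas$label)
  R
}

# one subject: T multivariate normal samples with marginal covariance R
# (after noise), optional AR(1) temporal structure preserving marginals
.simulate_subject <- function(R, n_t, noise_sd, ar) {
  n <- nrow(R)
  scale <- 1 + noise_sd^2
  # signal covariance chosen so corr(signal + noise) == R marginally
  S <- R * scale
  diag(S) <- diag(S) - noise_sd^2
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < -1e-8)
    stop("noise_sd too large for the requested correlation targets")
  sig <- MASS::mvrnorm(n_t, mu = rep(0, n), Sigma = S)
  if (ar > 0) {
    for (t in 2:n_t)
      sig[t, ] <- ar * sig[t - 1L, ] + sqrt(1 - ar^2) * sig[t, ]
  }
  x <- sig + matrix(stats::rnorm(n_t * n, sd = noise_sd), n_t, n)
  ts <- t(x)  # regions x timepoints
  rownames(ts) <- rownames(R)
  ts
}

#' Simulate a two-group cohort
#'
#' Draws every subject's regional time series from the group covariance
#' (plus white noise), reproducibly from the spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `cohort`: `controls` and `patients` (each a
#'   named list of regions x timepoints matrices), the `spec`, and the
#'   two group correlation targets.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  R_c <- build_covariance(spec, "control")
  R_p <- build_covariance(spec, "patient")
  set.seed(spec$seed)
  draw <- function(R, n_sub, prefix) {
    out <- lapply(seq_len(n_sub), function(i)
      .simulate_subject(R, spec$n_timepoints, spec$noise_sd,
                        spec$ar_coefficient))
    names(out) <- sprintf("%s%02d", prefix, seq_len(n_sub))
    out
  }
  structure(list(
    controls = draw(R_c, spec$n_controls, "HC"),
    patients = draw(R_p, spec$n_patients, "PT"),
    target_control = R_c,
    target_patient = R_p,
    spec = spec
  ), class = "cohort")
}

#' Write a cohort to delimited text files
#'
#' One CSV per subject (regions as rows, timepoints as columns, labels in
#' the first column) plus a `manifest.csv` recording subject id, group,
#' file and the generating seed.
#'
#' @param cohort A `cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (grp in c("controls", "patients")) {
    for (id in names(cohort[[grp]])) {
      file <- file.path(dir, paste0(id, ".csv"))
      ts <- cohort[[grp]][[id]]
      utils::write.csv(
        data.frame(label = rownames(ts), ts, check.names = FALSE),
        file, row.names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = id, group = sub("s$", "", grp), file = basename(file),
        seed = cohort$spec$seed)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Read a subject time-series file written by [write_cohort()]
#'
#' @param path CSV with a `label` column then one column per timepoint.
#' @return Regions x timepoints numeric matrix with region rownames.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"label" %in% names(df))
    stop("time-series file must have a 'label' column: ", path)
  m <- as.matrix(df[, setdiff(names(df), "label"), drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric time-series values in ", path)
  dimnames(m) <- list(df$label, NULL)
  m
}
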
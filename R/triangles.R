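#' @title 3-cycle triangle-area segregation statistic
#' @description Each unordered triple of regions defines a triangle whose
#'   sides are the three pairwise correlation coefficients. Its area,
#'   computed with Heron's formula, indexes the joint intensity of the
#'   three correlations; triples whose area reaches that of an equilateral
#'   triangle with side 0.6 are admitted as "significant" 3-cycles and
#'   summarised per network and for the whole brain.
#' @name triangle_segregation
NULL

# admission uses area >= thr - .AREA_TOL: populated minima in reference
# tables equal the rounded threshold itself, so the boundary is admissible
.AREA_TOL <- 1e-12

#' Heron's formula for a triangle area
#'
#' `A = sqrt(s (s-a) (s-b) (s-c))` with semi-perimeter
#' `s = (a + b + c) / 2`. Vectorized over the three sides.
#'
#' @param a,b,c Positive side lengths (here, correlation coefficients).
#' @return Numeric vector of areas; `NA` where the triangle inequality
#'   fails (strictly), i.e. the radicand is zero or negative.
#' @examples
#' heron_area(0.6, 0.6, 0.6)  # 0.1559 to 4 dp
#' @export
heron_area <- function(a, b, c) {
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(!is.finite(c)))
    stop("sides must be finite")
  if (any(a <= 0) || any(b <= 0) || any(c <= 0))
    stop("sides must be positive")
  s <- (a + b + c) / 2
  rad <- s * (s - a) * (s - b) * (s - c)
  out <- ifelse(rad > 0, sqrt(pmax(rad, 0)), NA_real_)
  as.numeric(out)
}

#' Triangle admission threshold
#'
#' Area of the hypothetical equilateral triangle whose sides all equal
#' `side`; the default 0.6 is the correlation intensity above which a
#' 3-cycle is considered representative.
#'
#' @param side Side length in `(0, 1]`.
#' @return The equilateral Heron area, `sqrt(3)/4 * side^2`.
#' @examples
#' round(area_threshold(0.6), 4)  # 0.1559
#' @export
area_threshold <- function(side = 0.6) {
  if (!is.numeric(side) || length(side) != 1L || is.na(side) ||
      side <= 0 || side > 1)
    stop("side must be a single value in (0, 1]")
  heron_area(side, side, side)
}

#' Enumerate admitted 3-cycle triangles
#'
#' Examines every unordered triple of nodes in scope, takes the three
#' pairwise correlations as sides, and admits the triple when its Heron
#' area reaches the admission threshold (to within a 1e-12 tolerance).
#' Triples with a zero side (no correlation after thresholding/zeroing)
#' or with geometrically invalid sides (triangle inequality violated,
#' possible with correlation sides) are excluded and counted in the
#' diagnostics.
#'
#' @param C An r-space [fc_matrix()].
#' @param indices Optional 1-based node indices restricting the scope
#'   (e.g. a resting-state network); default all nodes.
#' @param thr Admission threshold on the area; default
#'   `area_threshold(0.6)`.
#' @param min_side Optional side floor: triples are only considered when
#'   all three sides exceed this value (0 disables the restriction, the
#'   default — all possible triangles are examined and admission is purely
#'   by area).
#' @param scope Name recorded on the result.
#' @return A list of class `triangle_set`: `triangles` (data frame with
#'   node indices `i,j,k` (1-based), sides `a,b,c`, `area`), `scope`,
#'   `admission_threshold`, and diagnostics `n_candidates`,
#'   `n_zero_side`, `n_invalid_geometry`.
#' @export
enumerate_triangles <- function(C, indices = NULL, thr = area_threshold(0.6),
                                min_side = 0, scope = "whole_brain") {
  stopifnot(inherits(C, "fc_matrix"))
  if (fc_space(C) != "r") stop("triangle sides are taken on the r scale")
  v <- unclass(C)
  if (is.null(indices)) indices <- seq_len(nrow(v))
  indices <- sort(unique(as.integer(indices)))
  if (length(indices) < 3L)
    stop("triangle enumeration needs at least 3 nodes in scope (got ",
         length(indices), ")")
  trip <- utils::combn(indices, 3L)
  i <- trip[1L, ]; j <- trip[2L, ]; k <- trip[3L, ]
  a <- v[cbind(i, j)]
  b <- v[cbind(i, k)]
  c_ <- v[cbind(j, k)]
  n_cand <- length(i)

  pos <- a > min_side & b > min_side & c_ > min_side
  zero_side <- !(a > 0 & b > 0 & c_ > 0)
  n_zero <- sum(zero_side)

  area <- rep(NA_real_, n_cand)
  ok <- pos & !zero_side
  if (any(ok)) area[ok] <- heron_area(a[ok], b[ok], c_[ok])
  invalid <- ok & is.na(area)
  admitted <- !is.na(area) & area >= thr - .AREA_TOL

  structure(list(
    triangles = data.frame(
      i = i[admitted], j = j[admitted], k = k[admitted],
      a = a[admitted], b = b[admitted], c = c_[admitted],
      area = area[admitted]
    ),
    scope = scope,
    admission_threshold = thr,
    min_side = min_side,
    n_candidates = n_cand,
    n_zero_side = n_zero,
    n_invalid_geometry = sum(invalid)
  ), class = "triangle_set")
}

#' @export
print.triangle_set <- function(x, ...) {
  cat(sprintf(
    "<triangle_set> scope %s: %d admitted of %d triples (thr %.4f)\n",
    x$scope, nrow(x$triangles), x$n_candidates, x$admission_threshold))
  invisible(x)
}

.skewness_g1 <- function(x, adjusted = FALSE) {
  n <- length(x)
  if (n <= 2L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  g1 <- mean((x - m)^3) / m2^1.5
  if (adjusted) g1 * sqrt(n * (n - 1)) / (n - 2) else g1
}

#' Statistical estimators of a triangle set
#'
#' The summary row reported per group and scope: number of admitted
#' triangles and mean, median, skewness, sample standard deviation and
#' range (min, max) of their areas. Skewness is the moment-based
#' Fisher-Pearson `g1 = m3 / m2^(3/2)` by default (the adjusted
#' small-sample estimator is available); sets of 2 or fewer areas have
#' skewness 0, and for an empty set only `n` is reported.
#'
#' @param ts A `triangle_set` from [enumerate_triangles()].
#' @param adjusted_skewness Use the adjusted Fisher-Pearson estimator.
#' @return One-row data frame with columns `scope, n, mean, median,
#'   skewness, sd, min, max`.
#' @export
triangle_estimators <- function(ts, adjusted_skewness = FALSE) {
  stopifnot(inherits(ts, "triangle_set"))
  areas <- ts$triangles$area
  n <- length(areas)
  if (n == 0L)
    return(data.frame(scope = ts$scope, n = 0L, mean = NA_real_,
                      median = NA_real_, skewness = NA_real_, sd = NA_real_,
                      min = NA_real_, max = NA_real_))
  data.frame(
    scope = ts$scope,
    n = n,
    mean = mean(areas),
    median = stats::median(areas),
    skewness = .skewness_g1(areas, adjusted = adjusted_skewness),
    sd = if (n > 1L) stats::sd(areas) else 0,
    min = min(areas),
    max = max(areas)
  )
}
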
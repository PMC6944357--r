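test_that("Heron areas match closed forms and flag invalid geometry", {
  expect_equal(round(heron_area(0.6, 0.6, 0.6), 4), 0.1559)
  expect_equal(heron_area(1, 1, 1), sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(round(heron_area(1, 1, 1), 4), 0.4330)
  expect_true(is.na(heron_area(0.9, 0.1, 0.1)))   # inequality violated
  expect_true(is.na(heron_area(0.5, 0.3, 0.2)))   # degenerate (area 0)
  expect_error(heron_area(0, 0.5, 0.5), "positive")
  expect_error(heron_area(-0.1, 0.5, 0.5), "positive")
  # vectorized
  expect_equal(heron_area(c(0.6, 1), c(0.6, 1), c(0.6, 1)),
               c(heron_area(0.6, 0.6, 0.6), sqrt(3) / 4))
})

test_that("the admission threshold is the equilateral area of the side", {
  expect_equal(round(area_threshold(0.6), 4), 0.1559)
  expect_equal(area_threshold(1), sqrt(3) / 4, tolerance = 1e-12)
  expect_equal(area_threshold(0.6), heron_area(0.6, 0.6, 0.6))
  expect_error(area_threshold(0), "\\(0, 1\\]")
})

test_that("triangle enumeration counts candidates and admits at the boundary", {
  # uniform r = 0.6 over 12 nodes: all 220 triples sit exactly on the
  # boundary and are admitted
  m <- matrix(0.6, 12, 12); diag(m) <- 0
  ts <- enumerate_triangles(fc_matrix(m))
  expect_equal(ts$n_candidates, choose(12, 3))
  expect_equal(nrow(ts$triangles), 220L)
  # uniform r = 0.5: equilateral area ~0.1083 below threshold, none admitted
  m5 <- matrix(0.5, 12, 12); diag(m5) <- 0
  expect_equal(nrow(enumerate_triangles(fc_matrix(m5))$triangles), 0L)

  # 90-node scope examines choose(90, 3) triples
  big <- fc_matrix(matrix(0, 90, 90))
  ts90 <- enumerate_triangles(big)
  expect_equal(ts90$n_candidates, 117480L)
  expect_equal(ts90$n_zero_side, 117480L)

  expect_error(enumerate_triangles(fc_matrix(matrix(0, 2, 2))),
               "at least 3 nodes")
})

test_that("enumeration equals the exhaustive-triple oracle on seeded matrices", {
  set.seed(21)
  for (rep in 1:10) {
    C <- random_r_matrix(12, 0, 1)
    v <- unclass(C)
    v[v < 0.15] <- 0  # inject zero sides
    C <- fc_matrix(v)
    ts <- enumerate_triangles(C)
    orc <- oracle_triangles(unclass(C), area_threshold(0.6))
    expect_equal(nrow(ts$triangles), orc$n)
    expect_equal(sort(ts$triangles$area), sort(orc$areas), tolerance = 1e-12)
    expect_true(all(ts$triangles$area >= area_threshold(0.6) - 1e-12))
  }
})

test_that("admitted count is nonincreasing in the admission threshold", {
  set.seed(22)
  C <- random_r_matrix(15, 0, 1)
  thrs <- seq(0.10, 0.30, by = 0.02)
  ns <- vapply(thrs, function(t)
    nrow(enumerate_triangles(C, thr = t)$triangles), numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("raising one correlation affects only acute-bounded areas as expected", {
  # Heron's area is monotone in a side only up to the right-angle bound
  # a <= sqrt(b^2 + c^2); beyond it the triangle flattens and the area
  # shrinks. The property test states exactly that: triangles not using
  # the raised edge are untouched, and those using it weakly grow while
  # the raised side stays within the bound.
  set.seed(23)
  for (rep in 1:10) {
    C <- random_r_matrix(8, 0.2, 0.9)
    ts1 <- enumerate_triangles(C, thr = 0)   # every valid triple
    v0 <- unclass(C)
    up <- which(upper.tri(v0), arr.ind = TRUE)
    pick <- up[sample(nrow(up), 1), ]
    i <- pick[1]; j <- pick[2]
    v <- v0
    v[i, j] <- v[j, i] <- min(1, v[i, j] + runif(1, 0, 0.1))
    ts2 <- enumerate_triangles(fc_matrix(v), thr = 0)
    key <- function(d) paste(d$i, d$j, d$k)
    common <- merge(ts1$triangles, ts2$triangles, by = c("i", "j", "k"))
    uses_edge <- (common$i == i & common$j == j) |
      (common$i == i & common$k == j) | (common$j == i & common$k == j)
    # untouched triples keep their areas exactly
    expect_equal(common$area.y[!uses_edge], common$area.x[!uses_edge])
    # within the right-angle bound the raised side grows the area
    other2 <- with(common[uses_edge, , drop = FALSE], {
      sides_new <- cbind(a.y, b.y, c.y)
      sides_old <- cbind(a.x, b.x, c.x)
      raised <- abs(sides_new - sides_old) > 1e-15
      ok <- logical(nrow(sides_new))
      for (r in seq_len(nrow(sides_new))) {
        w <- which(raised[r, ])[1]
        rest <- sides_new[r, -w]
        ok[r] <- sides_new[r, w]^2 <= sum(rest^2) + 1e-15
      }
      ok
    })
    grew <- common$area.y[uses_edge] >= common$area.x[uses_edge] - 1e-12
    expect_true(all(grew[other2]))
  }
})

test_that("estimators match a direct moment oracle and handle tiny sets", {
  set.seed(24)
  areas <- runif(100, 0.16, 0.3)
  ts <- structure(list(
    triangles = data.frame(i = 1, j = 2, k = 3, a = 1, b = 1, c = 1,
                           area = areas),
    scope = "test", admission_threshold = 0, min_side = 0,
    n_candidates = 100L, n_zero_side = 0L, n_invalid_geometry = 0L),
    class = "triangle_set")
  est <- triangle_estimators(ts)
  m <- sum(areas) / 100
  m2 <- sum((areas - m)^2) / 100
  m3 <- sum((areas - m)^3) / 100
  expect_equal(est$mean, m, tolerance = 1e-12)
  expect_equal(est$median, sort(areas)[50:51] |> mean(), tolerance = 1e-12)
  expect_equal(est$skewness, m3 / m2^1.5, tolerance = 1e-12)
  expect_equal(est$sd, sqrt(sum((areas - m)^2) / 99), tolerance = 1e-12)
  expect_equal(c(est$min, est$max), range(areas))

  # N = 2 with equal areas: skewness 0, sd 0
  ts$triangles <- ts$triangles[c(1, 1), ]
  est2 <- triangle_estimators(ts)
  expect_equal(est2$n, 2L)
  expect_equal(est2$skewness, 0)
  expect_equal(est2$sd, 0)

  # empty set: only n reported
  ts$triangles <- ts$triangles[0, ]
  est0 <- triangle_estimators(ts)
  expect_equal(est0$n, 0L)
  expect_true(all(is.na(unlist(est0[c("mean", "median", "skewness",
                                      "sd", "min", "max")]))))
})
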
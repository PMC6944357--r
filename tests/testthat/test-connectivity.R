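test_that("pearson_matrix matches a direct covariance computation", {
  set.seed(11)
  ts <- matrix(rnorm(4 * 50), 4, 50,
               dimnames = list(paste0("R", 1:4), NULL))
  C <- pearson_matrix(ts)
  # direct formula oracle
  for (i in 1:4) for (j in 1:4) {
    if (i == j) { expect_identical(unclass(C)[i, j], 0); next }
    xi <- ts[i, ]; xj <- ts[j, ]
    r <- sum((xi - mean(xi)) * (xj - mean(xj))) /
      sqrt(sum((xi - mean(xi))^2) * sum((xj - mean(xj))^2))
    expect_equal(unclass(C)[i, j], max(r, 0), tolerance = 1e-12)
  }
  expect_equal(attr(C, "space"), "r")
})

test_that("autocorrelations and anti-correlations are zeroed", {
  x <- sin(seq(0, 6, length.out = 30))
  ts <- rbind(a = x, b = x + 0, c = -x)
  # identical series give off-diagonal 1; sign-flipped give 0 after clipping
  C <- pearson_matrix(ts + matrix(rnorm(90, sd = 1e-8), 3, 30))
  expect_equal(unclass(C)["a", "b"], 1, tolerance = 1e-6)
  expect_equal(unclass(C)["a", "c"], 0)
  expect_equal(diag(unclass(C)), c(a = 0, b = 0, c = 0))
})

test_that("constant rows are reported by region", {
  ts <- rbind(good = rnorm(20), flat = rep(1, 20))
  expect_error(pearson_matrix(ts), "flat")
})

test_that("Fisher transform round-trips and maps known values", {
  expect_equal(unclass(fisher_z(fc_matrix(matrix(0, 2, 2))))[1, 2], 0)
  m <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  z <- fisher_z(fc_matrix(m))
  expect_equal(unclass(z)[1, 2], atanh(0.5), tolerance = 1e-12)
  expect_equal(unclass(z)[1, 2], 0.5493, tolerance = 1e-4)

  set.seed(2)
  C <- random_r_matrix(8, 0, 0.95)
  expect_equal(unclass(inverse_fisher(fisher_z(C))), unclass(C),
               tolerance = 1e-12)
})

test_that("r = 1 entries are clipped, not infinite, under fisher_z", {
  m <- matrix(c(0, 1, 1, 0), 2, 2)
  z <- fisher_z(fc_matrix(m))
  expect_true(all(is.finite(unclass(z))))
})

test_that("group_mean averages in z space and preserves zeros", {
  m1 <- fc_matrix(matrix(c(0, 0.3, 0.3, 0), 2, 2))
  m2 <- fc_matrix(matrix(c(0, 0.7, 0.7, 0), 2, 2))
  g <- group_mean(list(m1, m2))
  expect_equal(unclass(g)[1, 2], tanh((atanh(0.3) + atanh(0.7)) / 2),
               tolerance = 1e-12)
  expect_equal(unclass(g)[1, 2], 0.5288, tolerance = 1e-4)

  # single subject is the identity
  set.seed(3)
  C <- random_r_matrix(6, 0, 0.9)
  expect_equal(unclass(group_mean(list(C))), unclass(C), tolerance = 1e-12)

  # all-zero cells stay zero
  z1 <- fc_matrix(matrix(0, 3, 3)); z2 <- fc_matrix(matrix(0, 3, 3))
  expect_equal(unclass(group_mean(list(z1, z2))), matrix(0, 3, 3),
               ignore_attr = TRUE)

  bad <- fc_matrix(matrix(0, 2, 2), labels = c("x", "y"))
  expect_error(group_mean(list(m1, bad)), "mismatch")
})

test_that("thresholding is strict at the boundary", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.5
  m[1, 3] <- m[3, 1] <- 0.51
  C <- fc_matrix(m)
  G <- apply_threshold(C, 0.5, "binary")
  expect_equal(connection_count(G), 2L)  # only the 0.51 edge, both cells
  expect_equal(unclass(G)[1, 2], 0)      # exactly-at-threshold removed

  W <- apply_threshold(C, 0.5, "weighted")
  expect_equal(unclass(W)[1, 3], 0.51)
  expect_equal(unclass(W)[1, 2], 0)

  set.seed(4)
  Cr <- random_r_matrix(10, 0.01, 0.99)
  expect_equal(unclass(apply_threshold(Cr, 0, "weighted")), unclass(Cr))
  expect_equal(connection_count(apply_threshold(Cr, 1, "binary")), 0L)
  expect_error(apply_threshold(Cr, 1.5), "\\[0, 1\\]")
})

test_that("connection counts use the directed (2x edge) convention", {
  G <- k12_minus_edge()
  expect_equal(connection_count(G), 130L)
  expect_equal(connection_count(fc_graph(matrix(0, 4, 4))), 0L)
  one <- matrix(0, 4, 4); one[1, 2] <- one[2, 1] <- 1
  expect_equal(connection_count(fc_graph(one)), 2L)
})

test_that("density sweep is correct and nonincreasing with nested edges", {
  m <- matrix(0.9, 12, 12); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0.1
  C <- fc_matrix(m)
  d <- density_sweep(C, thresholds = 0.5)
  expect_equal(d$density, 65 / 66, tolerance = 1e-12)

  set.seed(5)
  Cr <- random_r_matrix(20, 0, 1)
  sweep <- seq(0.40, 0.50, by = 0.01)
  d <- density_sweep(Cr, thresholds = sweep)
  expect_true(all(diff(d$density) <= 0))
  # edge-set nesting: every surviving edge at t2 survives at t1 <= t2
  prev <- NULL
  for (t in sweep) {
    keep <- unclass(apply_threshold(Cr, t, "binary"))
    if (!is.null(prev)) expect_true(all(keep <= prev))
    prev <- keep
  }
  # complete graph at threshold 0
  full <- fc_matrix(matrix(0.6, 5, 5) - diag(0.6, 5))
  expect_equal(density_sweep(full, 0)$density, 1)
})

test_that("operations preserve symmetry and the zero diagonal", {
  set.seed(6)
  for (rep in 1:20) {
    C <- random_r_matrix(8, 0, 0.99)
    for (M in list(fisher_z(C), group_mean(list(C, C)),
                   apply_threshold(C, runif(1), "weighted"),
                   apply_threshold(C, runif(1), "binary"))) {
      v <- unclass(M)
      expect_equal(max(abs(v - t(v))), 0)
      expect_equal(max(abs(diag(v))), 0)
    }
  }
})
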
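test_that("the complete-minus-one-edge 12-node graph reproduces the known panel", {
  G <- k12_minus_edge()

  deg <- node_degree(G)
  expect_equal(sort(unique(deg)), c(10L, 11L))
  expect_equal(mean(deg), 130 / 12)
  expect_equal(round(mean(deg), 2), 10.83)

  cc <- clustering_coefficient(G)
  s_cc <- nodal_summary(cc, deg)
  expect_equal(round(s_cc$mean, 2), 0.98)
  expect_equal(round(s_cc$sd, 4), 0.0071)

  le <- local_efficiency(G)
  s_le <- nodal_summary(le, deg)
  expect_equal(round(s_le$mean, 2), 0.99)
  expect_equal(round(s_le$sd, 4), 0.0035)

  cpl <- characteristic_path_length(G)
  expect_equal(as.numeric(cpl), 67 / 66)
  expect_equal(round(as.numeric(cpl), 3), 1.015)

  expect_equal(global_efficiency(G), 65.5 / 66)
  expect_equal(round(global_efficiency(G), 2), 0.99)
})

test_that("small named graphs give hand-computed metric values", {
  # 3-node path: degrees (1,2,1), CPL (1+1+2)/3, clustering all 0
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  G <- fc_graph(P)
  expect_equal(unname(node_degree(G)), c(1L, 2L, 1L))
  expect_equal(as.numeric(characteristic_path_length(G)), 4 / 3)
  expect_equal(unname(clustering_coefficient(G)), c(0, 0, 0))

  # triangle: everything 1
  Tr <- fc_graph(matrix(1, 3, 3) - diag(3))
  expect_equal(unname(clustering_coefficient(Tr)), rep(1, 3))
  expect_equal(unname(local_efficiency(Tr)), rep(1, 3))
  expect_equal(global_efficiency(Tr), 1)
  expect_equal(as.numeric(characteristic_path_length(Tr)), 1)

  # star: hub's neighbors unconnected
  S <- matrix(0, 5, 5); S[1, 2:5] <- S[2:5, 1] <- 1
  expect_equal(unname(clustering_coefficient(fc_graph(S))), rep(0, 5))

  # edgeless / isolated
  E <- fc_graph(matrix(0, 4, 4))
  expect_equal(unname(node_degree(E)), rep(0L, 4))
  expect_equal(global_efficiency(E), 0)
  expect_true(is.na(characteristic_path_length(E)))
  expect_false(graph_metrics(E)$computable)
})

test_that("all five metrics equal brute-force oracles on 200 random graphs", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(4:15, 1)
    G <- random_graph(n, runif(1, 0.15, 0.85))
    A <- unclass(G)

    expect_equal(unname(node_degree(G)), as.integer(rowSums(A)))
    expect_equal(unname(clustering_coefficient(G)), oracle_clustering(A),
                 tolerance = 1e-12)
    expect_equal(unname(local_efficiency(G)), oracle_local_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(global_efficiency(G), oracle_global_efficiency(A),
                 tolerance = 1e-12)
    cpl <- characteristic_path_length(G)
    expect_equal(as.numeric(cpl), oracle_cpl(A), tolerance = 1e-12)
  }
})

test_that("disconnected graphs average over reachable pairs only", {
  # two triangles, no bridge: all distances within components are 1
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  G <- fc_graph(A)
  cpl <- characteristic_path_length(G)
  expect_equal(as.numeric(cpl), 1)
  expect_equal(attr(cpl, "n_unreachable_pairs"), 18L)
  # 1/Inf = 0 for the 18 cross pairs: eff = 12/30
  expect_equal(global_efficiency(G), 12 / 30)

  # two isolated nodes
  expect_equal(global_efficiency(fc_graph(matrix(0, 2, 2))), 0)
})

test_that("adding an edge never decreases efficiency nor increases CPL", {
  set.seed(9)
  for (rep in 1:25) {
    G <- random_graph(8, 0.4)
    A <- unclass(G)
    off <- which(A == 0 & upper.tri(A), arr.ind = TRUE)
    if (nrow(off) == 0) next
    pick <- off[sample(nrow(off), 1), ]
    B <- A; B[pick[1], pick[2]] <- B[pick[2], pick[1]] <- 1
    G2 <- fc_graph(B)
    expect_gte(global_efficiency(G2), global_efficiency(G) - 1e-12)
    # CPL comparison on the original reachable-pair set
    D1 <- oracle_distances(A); D2 <- oracle_distances(B)
    reach <- is.finite(D1) & row(D1) != col(D1)
    if (any(reach))
      expect_lte(mean(D2[reach]), mean(D1[reach]) + 1e-12)
    expect_lte(global_efficiency(G2), 1)
    cpl <- characteristic_path_length(G2)
    if (!is.na(cpl)) expect_gte(as.numeric(cpl), 1)
  }
})

test_that("nodal summaries honour the include_isolated flag", {
  s <- nodal_summary(c(2, 0, 4), degrees = c(1L, 0L, 2L),
                     include_isolated = FALSE)
  expect_equal(s$mean, 3)
  expect_equal(s$n_used, 2L)
  s2 <- nodal_summary(c(2, 0, 4), degrees = c(1L, 0L, 2L),
                      include_isolated = TRUE)
  expect_equal(s2$mean, 2)

  expect_equal(nodal_summary(c(1, 1, 1), c(1L, 1L, 1L))$sd, 0)

  none <- nodal_summary(numeric(3), degrees = c(0L, 0L, 0L))
  expect_equal(none$n_used, 0L)
  expect_true(is.na(none$mean))

  # K12-e has no isolated nodes: both flags agree
  G <- k12_minus_edge()
  deg <- node_degree(G)
  expect_equal(nodal_summary(as.numeric(deg), deg, FALSE)$mean,
               nodal_summary(as.numeric(deg), deg, TRUE)$mean)
})
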
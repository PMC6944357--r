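# Brute-force oracles, independent of the implementation paths they check.

# All-pairs shortest-path distances by explicit breadth-first search.
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (u in frontier) nxt <- c(nxt, which(A[u, ] > 0))
      nxt <- unique(nxt[!is.finite(dist[nxt])])
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

oracle_global_efficiency <- function(A) {
  n <- nrow(A)
  if (n < 2) return(0)
  D <- oracle_distances(A)
  tot <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j)
    tot <- tot + if (is.finite(D[i, j])) 1 / D[i, j] else 0
  tot / (n * (n - 1))
}

oracle_cpl <- function(A) {
  D <- oracle_distances(A)
  vals <- c()
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && is.finite(D[i, j])) vals <- c(vals, D[i, j])
  if (length(vals) == 0) NA_real_ else mean(vals)
}

oracle_clustering <- function(A) {
  n <- nrow(A)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb))
      if (a < b && A[nb[a], nb[b]] > 0) links <- links + 1
    cc[i] <- 2 * links / (k * (k - 1))
  }
  cc
}

oracle_local_efficiency <- function(A) {
  n <- nrow(A)
  le <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) next
    le[i] <- oracle_global_efficiency(A[nb, nb, drop = FALSE])
  }
  le
}

# Exhaustive triple enumeration over an r matrix (area admission only).
oracle_triangles <- function(v, thr) {
  n <- nrow(v)
  out <- 0
  areas <- c()
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- v[i, j]; b <- v[i, k]; c_ <- v[j, k]
    if (a <= 0 || b <= 0 || c_ <= 0) next
    s <- (a + b + c_) / 2
    rad <- s * (s - a) * (s - b) * (s - c_)
    if (rad <= 0) next
    A <- sqrt(rad)
    if (A >= thr - 1e-12) { out <- out + 1; areas <- c(areas, A) }
  }
  list(n = out, areas = areas)
}

# Exact two-sided rank-sum p-value by enumeration of all group assignments.
oracle_ranksum_exact_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  obs <- sum(r[seq_len(n1)])
  combos <- utils::combn(length(pool), n1)
  sums <- apply(combos, 2, function(idx) sum(r[idx]))
  mu <- mean(sums)
  mean(abs(sums - mu) >= abs(obs - mu) - 1e-9)
}

random_graph <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up] <- stats::rbinom(length(up), 1, p)
  A <- A + t(A)
  fc_graph(A)
}

k12_minus_edge <- function() {
  A <- matrix(1, 12, 12)
  diag(A) <- 0
  A[1, 2] <- A[2, 1] <- 0
  fc_graph(A)
}

random_r_matrix <- function(n, lo = 0, hi = 1) {
  v <- matrix(0, n, n)
  up <- which(upper.tri(v))
  v[up] <- stats::runif(length(up), lo, hi)
  v <- v + t(v)
  fc_matrix(v, space = "r")
}
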
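# Brute-force oracles, independent of the package implementation: distances
# and shortest-path counts via adjacency-matrix powers, centralities from
# those, triangle enumeration by triple checking, a union-find for
# components, the BH step-up ladder, the pooled-variance t-test, and the
# exact hypergeometric tail.

rand_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = sprintf("v%02d", seq_len(n)))
}

adj_mat <- function(g) {
  as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
}

# distances and shortest-path counts: number of geodesics between i and j is
# the (i,j) entry of A^d at d = geodesic distance
bf_dist_paths <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n); diag(D) <- 0
  paths <- diag(1, n)
  Ad <- A
  for (d in seq_len(n - 1)) {
    newly <- is.infinite(D) & Ad > 0
    D[newly] <- d
    paths[newly] <- Ad[newly]
    Ad <- Ad %*% A
  }
  list(D = D, paths = paths)
}

bf_betweenness <- function(g, normalized = TRUE) {
  A <- adj_mat(g); n <- nrow(A)
  dp <- bf_dist_paths(A)
  btw <- numeric(n)
  if (n >= 3) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dp$D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dp$D[s, v]) && is.finite(dp$D[v, t]) &&
          dp$D[s, v] + dp$D[v, t] == dp$D[s, t])
        btw[v] <- btw[v] + dp$paths[s, v] * dp$paths[v, t] / dp$paths[s, t]
    }
  }
  if (normalized && n > 2) btw <- btw / ((n - 1) * (n - 2) / 2)
  stats::setNames(btw, igraph::V(g)$name)
}

bf_closeness <- function(g) {
  A <- adj_mat(g)
  D <- bf_dist_paths(A)$D
  out <- sapply(seq_len(nrow(A)), function(i) {
    comp <- which(is.finite(D[i, ]))
    if (length(comp) == 1) 0 else (length(comp) - 1) / sum(D[i, comp])
  })
  stats::setNames(out, igraph::V(g)$name)
}

bf_clustering <- function(g) {
  A <- adj_mat(g)
  out <- sapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (i in 1:(k - 1)) for (j in (i + 1):k)
      if (A[nb[i], nb[j]] > 0) tri <- tri + 1
    2 * tri / (k * (k - 1))
  })
  stats::setNames(out, igraph::V(g)$name)
}

bf_mean_neighbor_degree <- function(g) {
  A <- adj_mat(g)
  k <- rowSums(A)
  out <- sapply(seq_len(nrow(A)), function(v) {
    nb <- which(A[v, ] > 0)
    if (length(nb) == 0) 0 else mean(k[nb])
  })
  stats::setNames(out, igraph::V(g)$name)
}

bf_eigen_centrality <- function(g) {
  A <- adj_mat(g)
  n <- nrow(A)
  memb <- bf_components_membership(A)
  out <- numeric(n)
  for (c in unique(memb)) {
    idx <- which(memb == c)
    if (length(idx) == 1) { out[idx] <- 1; next }
    ev <- eigen(A[idx, idx, drop = FALSE], symmetric = TRUE)
    v <- abs(ev$vectors[, 1])
    out[idx] <- v / max(v)
  }
  stats::setNames(out, igraph::V(g)$name)
}

# union-find component membership on an adjacency matrix
bf_components_membership <- function(A) {
  n <- nrow(A)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n))
    if (A[i, j] > 0) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  vapply(seq_len(n), find, 1L)
}

bf_triangles <- function(g) {
  A <- adj_mat(g)
  nm <- igraph::V(g)$name
  n <- nrow(A)
  out <- list()
  if (n >= 3) for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n)
    if (A[i, j] > 0 && A[j, k] > 0 && A[i, k] > 0)
      out[[length(out) + 1]] <- sort(nm[c(i, j, k)])
  out
}

# BH step-up ladder: p_(i) * n / i with a cumulative minimum from the top
bh_oracle <- function(p) {
  n <- length(p)
  s <- sort(p, index.return = TRUE)
  adj <- pmin(1, rev(cummin(rev(s$x * n / seq_len(n)))))
  out <- numeric(n)
  out[s$ix] <- adj
  out
}

pooled_t_oracle <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  df <- n1 + n2 - 2
  s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / df
  t <- (mean(x2) - mean(x1)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df))
}

# exact upper-tail hypergeometric P[X >= k] by direct summation
hyper_tail_oracle <- function(k, N, K, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# sorted list-of-sets comparison helper
set_list_key <- function(sets) {
  unname(sort(vapply(sets, function(s) paste(sort(s), collapse = "|"),
                     "", USE.NAMES = FALSE)))
}
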
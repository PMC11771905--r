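# Shifted power iteration for the dominant eigenpair of a symmetric matrix.
# Adding sigma*I (sigma = max absolute row sum) makes every shifted eigenvalue
# non-negative, so the algebraically largest eigenvalue of M dominates and the
# iteration cannot oscillate (e.g. on bipartite adjacency spectra). Runs from
# two deterministic start vectors — the uniform vector and the index ramp —
# and keeps the eigenpair with the larger Rayleigh quotient, since a single
# fixed start can be orthogonal to the dominant eigenvector (the uniform
# start covers Perron-like vectors; the ramp covers sign-structured ones).
power_iteration <- function(M, tol = 1e-10, max_iter = 10000) {
  n <- nrow(M)
  if (n == 1) return(list(value = M[1, 1], vector = 1, iterations = 0))
  sigma <- max(rowSums(abs(M)))

  run <- function(v) {
    v <- v / sqrt(sum(v^2))
    it <- 0
    for (it in seq_len(max_iter)) {
      w <- as.vector(M %*% v) + sigma * v
      nw <- sqrt(sum(w^2))
      if (nw < .Machine$double.eps) break # eigenvalue -sigma; v is as good
      w <- w / nw
      done <- max(abs(w - v)) < tol
      v <- w
      if (done) break
    }
    list(value = as.numeric(v %*% (M %*% v)), vector = v, iterations = it)
  }

  a <- run(rep(1, n))
  b <- run(seq_len(n))
  if (a$value >= b$value) a else b
}

#' Per-node topological metrics
#'
#' For every node: degree `k`; local clustering coefficient
#' `C = 2T / (k (k - 1))` with `T` the number of triangles through the node
#' (defined 0 when `k < 2`); neighbourhood connectivity `C_N` (mean neighbour
#' degree); betweenness centrality `C_B` normalized by `(n-1)(n-2)/2`;
#' closeness `C_C = (n_comp - 1) / sum of distances` within the node's
#' connected component (0 for singleton components); and eigenvector
#' centrality `C_E`, computed per component by power iteration on the
#' component adjacency matrix and normalized so the maximum entry is 1.
#'
#' @param graph a simple undirected igraph graph.
#' @return A data.frame with columns `node`, `k`, `C`, `C_N`, `C_B`, `C_C`,
#'   `C_E`.
#' @export
node_metrics <- function(graph) {
  if (!igraph::is_simple(graph) || igraph::is_directed(graph))
    stop("graph must be simple and undirected")
  n <- igraph::vcount(graph)
  names <- igraph::V(graph)$name
  if (is.null(names)) names <- as.character(seq_len(n))
  k <- igraph::degree(graph)
  tri <- igraph::count_triangles(graph)
  C <- ifelse(k >= 2, 2 * tri / (k * (k - 1)), 0)
  C_N <- if (igraph::ecount(graph) == 0) rep(0, n) else {
    knn <- suppressWarnings(igraph::knn(graph)$knn)
    ifelse(is.finite(knn), knn, 0)
  }
  C_B <- if (n > 2)
    igraph::betweenness(graph, directed = FALSE) / ((n - 1) * (n - 2) / 2)
  else rep(0, n)
  C_C <- numeric(n)
  C_E <- numeric(n)
  comp <- igraph::components(graph)
  for (ci in seq_len(comp$no)) {
    idx <- which(comp$membership == ci)
    if (length(idx) == 1) {
      C_C[idx] <- 0
      C_E[idx] <- 1
      next
    }
    sub <- igraph::induced_subgraph(graph, idx)
    d <- igraph::distances(sub)
    C_C[idx] <- (length(idx) - 1) / rowSums(d)
    A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = FALSE))
    ev <- power_iteration(A)$vector
    ev <- abs(ev)
    C_E[idx] <- ev / max(ev)
  }
  data.frame(node = names, k = as.integer(k), C = C, C_N = C_N,
             C_B = C_B, C_C = C_C, C_E = C_E,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-degree mean profiles of the topological metrics
#'
#' Groups nodes by degree and reports, for each observed degree `k`, the
#' fraction of nodes `P(k)` and the arithmetic means of `C`, `C_N`, `C_B`,
#' `C_C`, `C_E` over nodes of that degree. Degrees with no nodes are absent.
#'
#' @param metrics output of [node_metrics()].
#' @return A data.frame with columns `k`, `p_k`, `C`, `C_N`, `C_B`, `C_C`,
#'   `C_E`, one row per observed degree, ascending.
#' @export
degree_profile <- function(metrics) {
  if (nrow(metrics) == 0) stop("empty metrics")
  ks <- sort(unique(metrics$k))
  rows <- lapply(ks, function(kk) {
    sub <- metrics[metrics$k == kk, , drop = FALSE]
    data.frame(k = kk, p_k = nrow(sub) / nrow(metrics),
               C = mean(sub$C), C_N = mean(sub$C_N), C_B = mean(sub$C_B),
               C_C = mean(sub$C_C), C_E = mean(sub$C_E))
  })
  out <- do.call(rbind, rows)
  stopifnot(abs(sum(out$p_k) - 1) < 1e-12)
  out
}
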
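#' Newman modularity of a partition
#'
#' `Q = sum_c [ e_c / m - (d_c / 2m)^2 ]` with `e_c` the number of edges
#' inside community `c`, `d_c` the total degree of its members, and `m` the
#' edge count of the graph.
#'
#' @param graph undirected igraph graph with at least one edge.
#' @param membership community assignment: named vector (by node name) or a
#'   vector aligned with the graph's vertices.
#' @return The modularity Q.
#' @export
modularity_q <- function(graph, membership) {
  m <- igraph::ecount(graph)
  if (m == 0) stop("graph has no edges")
  names_v <- igraph::V(graph)$name
  if (!is.null(names(membership))) {
    miss <- setdiff(names_v, names(membership))
    if (length(miss)) stop("node missing from partition: ",
                           paste(miss, collapse = ", "))
    membership <- membership[names_v]
  } else if (length(membership) != igraph::vcount(graph)) {
    stop("membership length must match vertex count")
  }
  k <- igraph::degree(graph)
  el <- igraph::as_edgelist(graph, names = TRUE)
  memb_of <- stats::setNames(membership, names_v)
  Q <- 0
  for (comm in unique(membership)) {
    inside <- names_v[membership == comm]
    e_c <- sum(memb_of[el[, 1]] == comm & memb_of[el[, 2]] == comm)
    d_c <- sum(k[inside])
    Q <- Q + e_c / m - (d_c / (2 * m))^2
  }
  unname(Q)
}

# Generalized modularity matrix over a vertex subset g (Newman's B_g):
# B_g(i,j) = A_ij - k_i k_j / 2m - delta_ij * sum_{l in g} (A_il - k_i k_l / 2m),
# with A, k, m taken from the full graph. Equals B itself when g is all nodes.
modularity_matrix_subset <- function(graph, members) {
  names_v <- igraph::V(graph)$name
  idx <- match(members, names_v)
  if (anyNA(idx)) stop("members not in graph")
  A_full <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  k <- igraph::degree(graph)
  m2 <- 2 * igraph::ecount(graph)
  A <- as.matrix(A_full[idx, idx, drop = FALSE])
  kg <- k[idx]
  B <- A - outer(kg, kg) / m2
  diag(B) <- diag(B) - (rowSums(A) - kg * sum(kg) / m2)
  dimnames(B) <- list(members, members)
  B
}

#' Leading-eigenvector modularity bisection of a community
#'
#' Builds the generalized modularity matrix over the member subset, finds
#' its leading eigenpair by deterministic shifted power iteration, and
#' proposes the split given by the eigenvector sign pattern (zero entries go
#' to the positive side). The split is divisible when the leading eigenvalue
#' and the modularity gain `delta_Q = s' B_g s / 4m` are both positive and
#' both sides are non-empty.
#'
#' @param graph the full undirected graph (degrees and `m` are global).
#' @param members character vector (>= 2) of node names to bisect; defaults
#'   to all nodes.
#' @param refine `"none"` (default) takes the raw eigenvector sign split;
#'   `"kl"` follows it with Kernighan-Lin-style single-node moves, greedily
#'   flipping the node with the best positive modularity gain until the
#'   split is single-move stable.
#' @return A `lev_split` list: `eigenvalue`, `sign_vector` (named +/-1),
#'   `delta_q`, `divisible`, `residual` (eigenpair residual inf-norm).
#' @export
lev_split <- function(graph, members = igraph::V(graph)$name,
                      refine = c("none", "kl")) {
  refine <- match.arg(refine)
  if (length(members) < 2) stop("member subset must have at least 2 nodes")
  B <- modularity_matrix_subset(graph, members)
  eig <- power_iteration(B)
  v <- eig$vector
  residual <- max(abs(B %*% v - eig$value * v))
  s <- ifelse(v >= 0, 1, -1)
  if (refine == "kl" && any(s > 0) && any(s < 0)) {
    # flipping node i changes s'Bs by -4 s_i ((Bs)_i - B_ii s_i)
    for (pass in seq_len(10 * length(s))) {
      Bs <- as.vector(B %*% s)
      gains <- -4 * s * (Bs - diag(B) * s)
      # moving the last node of a side would empty it
      lone <- (s == -1 & sum(s == -1) == 1) | (s == 1 & sum(s == 1) == 1)
      gains[lone] <- -Inf
      best <- which.max(gains)
      if (gains[best] <= 1e-12) break
      s[best] <- -s[best]
    }
  }
  m <- igraph::ecount(graph)
  delta_q <- as.numeric(s %*% B %*% s) / (4 * m)
  tol <- 1e-9
  divisible <- eig$value > tol && delta_q > tol &&
    any(s > 0) && any(s < 0)
  structure(list(eigenvalue = eig$value,
                 sign_vector = stats::setNames(s, members),
                 delta_q = delta_q, divisible = divisible,
                 residual = residual),
            class = "lev_split")
}

#' Enumerate triangle (G(3,3)) motifs
#'
#' All unordered node triples with all three internal edges, each listed
#' once, optionally restricted to a member subset.
#'
#' @param graph undirected igraph graph.
#' @param members optional node-name subset; triangles must lie entirely
#'   inside it.
#' @return List of length-3 character vectors (sorted within each triple).
#' @export
find_triangles <- function(graph, members = NULL) {
  g <- if (is.null(members)) graph else
    igraph::induced_subgraph(graph, members)
  tri <- igraph::triangles(g)
  if (length(tri) == 0) return(list())
  nm <- igraph::V(g)$name[as.integer(tri)]
  mat <- matrix(nm, ncol = 3, byrow = TRUE)
  lapply(seq_len(nrow(mat)), function(i) sort(mat[i, ]))
}

#' Dotted-path community label from child indices
#'
#' Root is "C"; child i of the root is "Ci"; deeper levels append ".i", so
#' the path 2 -> 3 -> 4 -> 1 labels "C2.3.4.1".
#'
#' @param indices integer vector of 1-based child indices from the root
#'   down; empty for the root itself.
#' @return The label string.
#' @export
community_label <- function(indices) {
  if (length(indices) == 0) "C" else
    paste0("C", paste(indices, collapse = "."))
}

# order communities for child numbering: decreasing size, ties by smallest
# member symbol
order_children <- function(member_sets) {
  sizes <- vapply(member_sets, length, 1L)
  firsts <- vapply(member_sets, function(s) sort(s)[1], "")
  order(-sizes, firsts)
}

is_triangle_set <- function(graph, members) {
  length(members) == 3 &&
    igraph::ecount(igraph::induced_subgraph(graph, members)) == 3
}

has_triangle <- function(graph, members) {
  sum(igraph::count_triangles(igraph::induced_subgraph(graph, members))) > 0
}

#' Recursive leading-eigenvector decomposition to triangle motifs
#'
#' The whole graph is the level-0 root community "C". Each community is
#' split by [lev_split()] into the two sign groups; children are numbered
#' 1..n in order of decreasing size (ties by smallest member symbol) and
#' labelled in dotted-path notation. Recursion stops at a community that is
#' exactly a triangle (a terminal G(3,3) motif leaf), has fewer than 3
#' members, is indivisible (non-positive leading eigenvalue or modularity
#' gain), or sits at `max_level`. Communities without any triangle are kept
#' in the tree but flagged `has_motif = FALSE`.
#'
#' Two recursion scopes are offered. `"local"` (default) treats each
#' community's induced subgraph as a standalone network and re-applies the
#' leading-eigenvector method to it, as when community detection is rerun
#' module-by-module; divisibility is judged against the subgraph's own
#' modularity, so decomposition typically continues down to terminal
#' triangle motifs. Disconnected communities are first split into their
#' connected components. `"global"` is Newman's classical recursion on the
#' generalized modularity matrix `B_g` of the full graph: every accepted
#' split strictly increases the global modularity, and recursion therefore
#' usually stops above the motif scale; component splitting then applies
#' only to a disconnected input graph (a virtual root).
#'
#' @param graph undirected igraph graph, non-empty.
#' @param max_level maximum depth, or `NULL` (default) for unbounded.
#' @param scope `"local"` (default) or `"global"`; see Details.
#' @param refine bisection refinement passed to [lev_split()].
#' @return A `decomposition_tree`: list with `root` (nested community
#'   nodes), `max_level` (deepest leaf level), `motif_leaves` (list of leaf
#'   nodes).
#' @export
recursive_decompose <- function(graph, max_level = NULL,
                                scope = c("local", "global"),
                                refine = c("none", "kl")) {
  scope <- match.arg(scope)
  refine <- match.arg(refine)
  if (igraph::vcount(graph) == 0) stop("empty graph")
  if (is.null(igraph::V(graph)$name))
    graph <- igraph::set_vertex_attr(graph, "name",
                                     value = as.character(seq_len(igraph::vcount(graph))))

  build <- function(members, path, level) {
    node <- list(label = community_label(path), level = level,
                 members = sort(members),
                 has_motif = has_triangle(graph, members),
                 is_motif_leaf = is_triangle_set(graph, members),
                 children = list())
    if (node$is_motif_leaf || length(members) < 3 ||
        (!is.null(max_level) && level >= max_level))
      return(node)
    sub <- igraph::induced_subgraph(graph, members)
    comp <- igraph::components(sub)
    if (comp$no > 1 && (scope == "local" || level == 0)) {
      parts <- split(igraph::V(sub)$name, comp$membership)
    } else {
      sp <- if (scope == "local") lev_split(sub, refine = refine)
            else lev_split(graph, members, refine = refine)
      if (!sp$divisible) return(node)
      parts <- split(names(sp$sign_vector), sp$sign_vector > 0)
    }
    ord <- order_children(parts)
    node$children <- lapply(seq_along(ord), function(i) {
      build(parts[[ord[i]]], c(path, i), level + 1)
    })
    node
  }

  root <- build(sort(igraph::V(graph)$name), integer(0), 0)
  leaves <- list(); depth <- 0
  walk <- function(nd) {
    if (length(nd$children) == 0) {
      depth <<- max(depth, nd$level)
      if (nd$is_motif_leaf) leaves[[length(leaves) + 1]] <<- nd
    } else {
      for (ch in nd$children) walk(ch)
    }
  }
  walk(root)
  structure(list(root = root, max_level = depth, motif_leaves = leaves),
            class = "decomposition_tree")
}

#' @export
print.decomposition_tree <- function(x, ...) {
  cat(sprintf("decomposition_tree: %d member(s), depth %d, %d motif leaf/leaves\n",
              length(x$root$members), x$max_level, length(x$motif_leaves)))
  invisible(x)
}

#' Motif-leaf path labels and members
#'
#' One row per terminal triangle motif, with its dotted-path label and its
#' three member genes sorted alphabetically.
#'
#' @param tree a [recursive_decompose()] tree.
#' @return data.frame with columns `leaf_label`, `members` (comma-joined).
#' @export
label_paths <- function(tree) {
  stopifnot(inherits(tree, "decomposition_tree"))
  if (length(tree$motif_leaves) == 0)
    return(data.frame(leaf_label = character(0), members = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    leaf_label = vapply(tree$motif_leaves, function(l) l$label, ""),
    members = vapply(tree$motif_leaves,
                     function(l) paste(sort(l$members), collapse = ","), ""),
    stringsAsFactors = FALSE)
}

#' Flatten a decomposition tree to one row per community
#'
#' @param tree a [recursive_decompose()] tree.
#' @return data.frame with columns `label`, `level`, `size`, `has_motif`,
#'   `is_motif_leaf`, `members` (comma-joined).
#' @export
tree_table <- function(tree) {
  rows <- list()
  walk <- function(nd) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = nd$label, level = nd$level, size = length(nd$members),
      has_motif = nd$has_motif, is_motif_leaf = nd$is_motif_leaf,
      members = paste(nd$members, collapse = ","),
      stringsAsFactors = FALSE)
    for (ch in nd$children) walk(ch)
  }
  walk(tree$root)
  do.call(rbind, rows)
}

#' Communities of the tree at a given level
#'
#' @param tree a [recursive_decompose()] tree.
#' @param level depth to cut at; communities that stopped earlier are
#'   carried down unchanged, so the cut is a partition of the root.
#' @return Named list of member-name vectors.
#' @export
level_partition <- function(tree, level) {
  out <- list()
  walk <- function(nd) {
    if (nd$level == level || length(nd$children) == 0) {
      out[[nd$label]] <<- nd$members
    } else {
      for (ch in nd$children) walk(ch)
    }
  }
  walk(tree$root)
  out
}
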
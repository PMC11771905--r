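#' Generate a two-group expression matrix with planted effects
#'
#' Control samples are drawn `Normal(baseline_g, sigma_g)` on the log2
#' scale; case samples are shifted by `+effect_lfc` for half of the planted
#' genes and `-effect_lfc` for the other half. Gene baselines are uniform
#' on \[6, 12\] (typical log2 intensities) and gene-wise standard deviations
#' come from a scaled inverse-chi-square prior
#' `sigma_g^2 ~ d0 * s0^2 / chisq(d0)`, giving the variance heterogeneity a
#' moderated t-test assumes.
#'
#' @param n_genes total genes. Default 2000.
#' @param n_per_group samples per group. Default 6 (a 12-sample two-group
#'   design).
#' @param n_deg planted differential genes (half up, half down).
#'   Default 200.
#' @param effect_lfc absolute planted log2 fold change. Default 2.
#' @param var_prior_df,var_prior_s2 scaled inverse-chi-square parameters of
#'   the gene variance prior. Defaults 4 and 0.09 (sigma around 0.3).
#' @param seed integer seed; identical seeds give identical output.
#' @return list with `matrix` (an [expression_matrix()]) and `truth`
#'   (data.frame `gene`, `is_deg`, `true_lfc`).
#' @export
gen_expression <- function(n_genes = 2000, n_per_group = 6, n_deg = 200,
                           effect_lfc = 2, var_prior_df = 4,
                           var_prior_s2 = 0.09, seed = 1) {
  if (n_deg > n_genes) stop("n_deg must not exceed n_genes")
  if (n_per_group < 2) stop("need at least 2 samples per group")
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  baseline <- stats::runif(n_genes, 6, 12)
  sigma <- sqrt(var_prior_df * var_prior_s2 /
                  stats::rchisq(n_genes, var_prior_df))
  true_lfc <- numeric(n_genes)
  if (n_deg > 0) {
    idx <- seq_len(n_deg) # planted genes are the first n_deg symbols
    n_up <- ceiling(n_deg / 2)
    true_lfc[idx] <- rep(c(effect_lfc, -effect_lfc),
                         c(n_up, n_deg - n_up))
  }
  n_tot <- 2 * n_per_group
  vals <- matrix(stats::rnorm(n_genes * n_tot,
                              mean = baseline, sd = sigma),
                 nrow = n_genes, ncol = n_tot)
  case_cols <- n_per_group + seq_len(n_per_group)
  vals[, case_cols] <- vals[, case_cols] + true_lfc
  rownames(vals) <- genes
  colnames(vals) <- c(sprintf("ctrl_%02d", seq_len(n_per_group)),
                      sprintf("case_%02d", seq_len(n_per_group)))
  groups <- rep(c("control", "case"), each = n_per_group)
  list(matrix = expression_matrix(vals, groups),
       truth = data.frame(gene = genes, is_deg = true_lfc != 0,
                          true_lfc = true_lfc, stringsAsFactors = FALSE))
}

# deterministic Ravasz-style hierarchical graph: start from a clique of
# `clique_size` nodes (node 1 the hub); at each replication step make
# clique_size - 1 copies of the current graph and join every peripheral node
# of the copies to the original hub. n = clique_size^levels.
hierarchical_graph <- function(clique_size = 5, levels = 2) {
  if (clique_size < 3) stop("clique_size must be at least 3")
  if (levels < 1) stop("levels must be at least 1")
  edges <- t(utils::combn(seq_len(clique_size), 2))
  peripheral <- 2:clique_size
  n <- clique_size
  if (levels > 1) for (step in 2:levels) {
    new_edges <- edges
    new_periph <- peripheral
    for (copy in seq_len(clique_size - 1)) {
      off <- copy * n
      new_edges <- rbind(new_edges, edges + off)
      new_periph <- c(new_periph, peripheral + off)
      # peripheral nodes of this copy attach to the root hub (node 1)
      new_edges <- rbind(new_edges, cbind(1L, peripheral + off))
    }
    edges <- new_edges
    peripheral <- new_periph
    n <- n * clique_size
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::set_vertex_attr(igraph::simplify(g), "name",
                          value = sprintf("N%04d", seq_len(n)))
}

#' Generate a benchmark graph with known structure
#'
#' Models: `ba` preferential attachment (degree exponent near 3),
#' `hierarchical` deterministic replication of a clique motif (clustering
#' falls off as 1/k), `planted_partition` stochastic block model with
#' `blocks` equal groups, `modular` a two-scale nested block model whose
#' bottom-level blocks are triangles (`supers` super-communities of
#' `tri_per` triangles each, triangles internally complete, linked with
#' probability `p_super` inside a super-community and `p_out` across), and
#' `er` Erdos-Renyi as a null. All outputs are simple undirected graphs
#' with node names.
#'
#' @param model one of `"ba"`, `"hierarchical"`, `"planted_partition"`,
#'   `"modular"`, `"er"`.
#' @param n nodes (`ba`, `er`, and per-block size for
#'   `planted_partition`).
#' @param m edges added per step for `ba`. Default 3.
#' @param clique_size,levels `hierarchical` parameters; node count is
#'   `clique_size^levels`.
#' @param blocks number of planted blocks. Default 2.
#' @param p_in,p_out within/between-block edge probabilities.
#'   Defaults 0.9 / 0.05.
#' @param supers,tri_per,p_super `modular` parameters: super-community
#'   count, triangles per super-community, and the within-super linking
#'   probability (node count is `3 * supers * tri_per`). Defaults 5, 5,
#'   0.08.
#' @param p edge probability for `er`. Default 0.05.
#' @param seed integer seed (ignored by the deterministic `hierarchical`
#'   model).
#' @return list with `graph` (igraph) and `truth` (`NULL`, or planted
#'   block membership as a named vector for `planted_partition` and
#'   `modular` — for `modular` the triangle index, with attribute
#'   `"super"` giving the super-community index).
#' @export
gen_graph <- function(model = c("ba", "hierarchical", "planted_partition",
                                "modular", "er"),
                      n = 100, m = 3, clique_size = 5, levels = 2,
                      blocks = 2, p_in = 0.9, p_out = 0.05,
                      supers = 5, tri_per = 5, p_super = 0.08,
                      p = 0.05, seed = 1) {
  model <- match.arg(model)
  set.seed(seed)
  truth <- NULL
  g <- switch(model,
    ba = {
      if (n < 2 || m < 1) stop("ba needs n >= 2 and m >= 1")
      igraph::sample_pa(n, m = m, directed = FALSE)
    },
    hierarchical = hierarchical_graph(clique_size, levels),
    planted_partition = {
      if (blocks < 2 || n < 2) stop("need at least 2 blocks of >= 2 nodes")
      sizes <- rep(n, blocks)
      pref <- matrix(p_out, blocks, blocks)
      diag(pref) <- p_in
      gg <- igraph::sample_sbm(sum(sizes), pref.matrix = pref,
                               block.sizes = sizes)
      truth <- rep(seq_len(blocks), each = n)
      gg
    },
    modular = {
      if (supers < 1 || tri_per < 1) stop("need supers >= 1 and tri_per >= 1")
      nb <- supers * tri_per
      pref <- matrix(p_out, nb, nb)
      for (s in seq_len(supers)) {
        idx <- ((s - 1) * tri_per + 1):(s * tri_per)
        pref[idx, idx] <- p_super
      }
      diag(pref) <- 1 # each bottom block is a complete triangle
      gg <- igraph::sample_sbm(3 * nb, pref.matrix = pref,
                               block.sizes = rep(3, nb))
      truth <- rep(seq_len(nb), each = 3)
      attr(truth, "super") <- rep(rep(seq_len(supers), each = tri_per),
                                  each = 3)
      gg
    },
    er = igraph::sample_gnp(n, p))
  g <- igraph::simplify(g)
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = sprintf("N%04d",
                                                 seq_len(igraph::vcount(g))))
  if (!is.null(truth)) names(truth) <- igraph::V(g)$name
  list(graph = g, truth = truth)
}

#' Draws from a power-law distribution
#'
#' Continuous draws use inverse-CDF sampling
#' `x = xmin * (1 - u)^(-1/(alpha-1))`; discrete draws invert a precomputed
#' zeta CDF table (exact up to a far-tail cutoff, beyond which the standard
#' continuous approximation to the zeta tail is used).
#'
#' @param n number of draws.
#' @param alpha exponent, must exceed 1.
#' @param xmin lower bound of support. Default 1.
#' @param discrete logical. Default `FALSE`.
#' @param seed optional integer seed.
#' @return Numeric vector of draws, all `>= xmin`.
#' @export
sample_powerlaw <- function(n, alpha, xmin = 1, discrete = FALSE,
                            seed = NULL) {
  if (alpha <= 1) stop("alpha must exceed 1")
  if (xmin < 1 && discrete) stop("discrete support starts at xmin >= 1")
  if (!is.null(seed)) set.seed(seed)
  cpp_sample_powerlaw(as.integer(n), alpha, xmin, discrete)
}

#' Dump a graph as a score-1 interaction table
#'
#' @param graph an igraph graph.
#' @return An [interaction_table()] with every edge scored 1.0, suitable as
#'   synthetic input to [build_network()].
#' @export
graph_to_interactions <- function(graph) {
  el <- igraph::as_data_frame(graph, what = "edges")
  interaction_table(data.frame(protein_a = el$from, protein_b = el$to,
                               combined_score = 1.0,
                               stringsAsFactors = FALSE))
}
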
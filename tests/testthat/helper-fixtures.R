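# Shared fixtures built in code.

# tiny expression matrix with explicit group means
toy_expression <- function(case_mean, ctrl_mean, n_per_group = 3, sd = 0,
                           n_genes = length(case_mean), seed = 1) {
  set.seed(seed)
  vals <- matrix(0, n_genes, 2 * n_per_group)
  for (gidx in seq_len(n_genes)) {
    vals[gidx, ] <- c(stats::rnorm(n_per_group, ctrl_mean[gidx], sd),
                      stats::rnorm(n_per_group, case_mean[gidx], sd))
  }
  rownames(vals) <- sprintf("g%d", seq_len(n_genes))
  colnames(vals) <- c(sprintf("c%d", seq_len(n_per_group)),
                      sprintf("t%d", seq_len(n_per_group)))
  expression_matrix(vals, rep(c("control", "case"), each = n_per_group))
}

# two triangles joined by a single bridge edge (c-d)
two_triangle_graph <- function() {
  igraph::make_graph(~ a - b, a - c, b - c, c - d, d - e, d - f, e - f)
}

# the 5-record toy DEG table used for threshold-semantics checks
toy_deg_table <- function() {
  data.frame(gene = paste0("g", 1:5),
             log2fc = c(1.2, -1.0, 0.9, 2.0, -3.0),
             p = c(0.01, 0.04, 0.001, 0.06, 0.01),
             padj = c(0.01, 0.05, 0.001, 0.04, 0.06),
             stringsAsFactors = FALSE)
}

# synthetic end-to-end inputs: planted DEGs carry the node names of a
# two-scale modular graph (triangle bottom blocks) so the screened genes
# reconstruct a network that decomposes down to motif leaves
make_synthetic_inputs <- function(seed = 1, n_genes = 600, n_deg = 150,
                                  n_per_group = 6, effect_lfc = 2,
                                  supers = 5, tri_per = 5) {
  ex <- gen_expression(n_genes = n_genes, n_per_group = n_per_group,
                       n_deg = n_deg, effect_lfc = effect_lfc, seed = seed)
  gr <- gen_graph("modular", supers = supers, tri_per = tri_per,
                  seed = seed + 1)
  n_nodes <- igraph::vcount(gr$graph)
  stopifnot(n_nodes <= n_deg)
  g <- igraph::set_vertex_attr(gr$graph, "name",
                               value = ex$truth$gene[seq_len(n_nodes)])
  list(matrix = ex$matrix, truth = ex$truth, graph = g,
       interactions = graph_to_interactions(g))
}
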
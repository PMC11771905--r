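#!/usr/bin/env Rscript
# Simulate the study inputs: a 12-sample two-group expression matrix with
# planted log2 effects, and a scored interaction table whose network has
# two-scale modular structure ending in triangle motifs. The planted
# differential genes carry the network's node names, so the downstream
# screen reconstructs the graph.
suppressPackageStartupMessages(library(keyregnet))

seed <- 1
out <- "results"
dir.create(out, showWarnings = FALSE)

ex <- gen_expression(n_genes = 600, n_per_group = 6, n_deg = 150,
                     effect_lfc = 2, seed = seed)
gr <- gen_graph("modular", supers = 5, tri_per = 5, seed = seed + 1)
n_nodes <- igraph::vcount(gr$graph)
g <- igraph::set_vertex_attr(gr$graph, "name",
                             value = ex$truth$gene[seq_len(n_nodes)])

write_expression(ex$matrix, file.path(out, "expression.tsv"),
                 file.path(out, "groups.tsv"))
utils::write.table(ex$truth, file.path(out, "truth.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
utils::write.table(graph_to_interactions(g),
                   file.path(out, "interactions.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d genes x %d samples; %d planted DEGs (|log2FC| = 2)\n",
            nrow(ex$matrix$values), ncol(ex$matrix$values),
            sum(ex$truth$is_deg)))
cat(sprintf("interaction table: %d nodes, %d scored pairs (5 super-communities x 5 triangles)\n",
            n_nodes, igraph::ecount(g)))
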
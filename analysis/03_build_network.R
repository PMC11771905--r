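#!/usr/bin/env Rscript
# Build the interaction network over the screened DEGs, keeping pairs with
# combined score strictly above 0.4.
suppressPackageStartupMessages(library(keyregnet))

deg <- read_deg_table("results/degs.tsv")
degs <- deg$gene[deg$direction != "none"]
tab <- read_interactions("results/interactions.tsv", dialect = "plain_tsv")
net <- build_network(tab, degs, score_min = 0.4)
write_network(net, "results/network.tsv")

comps <- connected_components(net)
cat(sprintf("network: %d nodes, %d edges, %d connected component(s) (largest %d)\n",
            igraph::vcount(net), igraph::ecount(net), length(comps),
            length(comps[[1]])))
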
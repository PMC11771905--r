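#!/usr/bin/env Rscript
# Hypergeometric over-representation of the key regulators against a
# gene-set collection, with the network's node set as the universe. The
# collection here is synthetic (the super-community memberships of the
# simulated graph); any GMT file can be substituted.
suppressPackageStartupMessages(library(keyregnet))

net <- read_network("results/network.tsv")
keyreg <- utils::read.delim("results/keyreg.tsv")
truth <- utils::read.delim("results/truth.tsv")

# synthetic gene sets: one per simulated super-community (15 genes each)
net_genes <- igraph::V(net)$name
ord <- order(match(net_genes, truth$gene))
gmt <- "results/supersets.gmt"
sets <- split(net_genes[ord], ceiling(seq_along(net_genes) / 15))
writeLines(vapply(names(sets), function(nm)
  paste(c(paste0("super", nm), "synthetic super-community", sets[[nm]]),
        collapse = "\t"), ""), gmt)

coll <- read_gmt(gmt, universe = net_genes)
res <- hypergeom_ora(unique(keyreg$gene), coll)
utils::write.table(res, "results/enrichment.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

cat(sprintf("ORA over %d sets (universe %d genes, query %d regulators):\n",
            nrow(res), res$universe_N[1], res$query_n[1]))
print(res[, c("set_name", "overlap_k", "set_K", "fold_enrichment",
              "p_value", "fdr")])
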
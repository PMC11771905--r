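#!/usr/bin/env Rscript
# Screen differentially expressed genes: log2 fold change (case - control),
# moderated t-test with empirical-Bayes variance shrinkage, BH correction,
# and the |log2FC| >= 1, p < 0.05, padj <= 0.05 thresholds.
suppressPackageStartupMessages(library(keyregnet))

ex <- read_expression("results/expression.tsv", "results/groups.tsv")
deg <- screen_degs(ex, lfc_min = 1, p_max = 0.05, padj_max = 0.05)
write_deg_table(deg, "results/degs.tsv")

counts <- attr(deg, "counts")
cat(sprintf("tested %d genes: %d DEGs (%d up, %d down)\n",
            nrow(deg), sum(deg$direction != "none"),
            counts["up"], counts["down"]))
truth <- utils::read.delim("results/truth.tsv")
called <- deg$gene[deg$direction != "none"]
cat(sprintf("planted recovery: %d/%d planted genes called; %d null genes passed\n",
            sum(truth$gene[truth$is_deg] %in% called), sum(truth$is_deg),
            sum(called %in% truth$gene[!truth$is_deg])))
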
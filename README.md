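# keyregnet

Network-theoretic discovery of **key regulator genes** from two-group
expression data. Given a gene × sample expression matrix (control vs case)
and a scored gene–gene interaction table (STRING-style), the package runs
the full chain:

1. **DEG screening** — per-gene log2 fold change (difference of log2 group
   means), a moderated t-test with empirical-Bayes variance shrinkage
   (posterior variance `(d0·s0² + d·s²)/(d0 + d)`, prior estimated by
   moment matching on the log gene variances), Benjamini–Hochberg
   correction, and the thresholds `|log2FC| ≥ 1`, `p < 0.05`,
   `padj ≤ 0.05`.
2. **Network construction** — undirected simple graph over the DEGs,
   keeping interactions with combined score strictly `> 0.4`.
3. **Topological profiling** — per node: degree `k`, clustering
   coefficient `C = 2T/(k(k−1))`, neighbourhood connectivity `C_N` (mean
   neighbour degree), betweenness `C_B`, closeness `C_C`, eigenvector
   centrality `C_E`; plus per-degree mean profiles.
4. **Power-law fitting** — the degree distribution is fitted with the
   Clauset maximum-likelihood procedure (KS-minimizing `xmin`, exponent by
   MLE, semi-parametric bootstrap goodness-of-fit over 2500 resamples;
   plausible when boot `p > 0.1` and KS `D ≤ 0.35`); the profiles
   `P(k) ~ k^(−α)`, `C(k) ~ k^(−β)`, `C_N(k) ~ k^(+φ)`,
   `C_B(k) ~ k^γ`, `C_C(k) ~ k^δ`, `C_E(k) ~ k^ψ` are fitted by log-log
   least squares, and the exponent signs classify the network: weak
   hierarchy when `C(k)` decays with `|β| < 1` and `0 < φ ≤ 0.5`, strong
   when `|β| ≥ 1`, assortative mixing when `φ > 0`.
5. **Community decomposition** — Newman's leading-eigenvector (LEV)
   modularity bisection built from the modularity matrix
   `B_ij = A_ij − k_i k_j / 2m`, applied recursively to produce a
   hierarchical tree with dotted-path labels (`C → C2 → C2.3 → …`) whose
   terminal leaves are triangle motifs, i.e. `G(3,3)` subgraphs (3 nodes,
   3 edges).
6. **Key-regulator tracing** — the genes persisting from the root down to
   a terminal triangle motif (equivalently, the union of motif-leaf
   members; their count is 3 × the number of motif leaves), summarized
   with their network statistics and a low-degree-bridge flag.
7. **Over-representation analysis** — hypergeometric upper-tail p-values
   and fold enrichment `(k/n)/(K/N)` of the regulators against GMT gene
   sets, BH-corrected across the collection.

A synthetic-data module (`gen_expression`, `gen_graph`,
`sample_powerlaw`) generates expression matrices with planted effects and
benchmark graphs (preferential attachment, deterministic hierarchical,
planted partition, nested triangle-block modular) so every stage is
testable without external downloads.

## Worked example

Simulate a 12-sample study with 150 planted differential genes whose
network has five super-communities of five triangles each, then run the
whole chain:

```r
library(keyregnet)

sim <- gen_expression(n_genes = 600, n_per_group = 6, n_deg = 150,
                      effect_lfc = 2, seed = 1)
net <- gen_graph("modular", supers = 5, tri_per = 5, seed = 2)
g   <- igraph::set_vertex_attr(net$graph, "name",
         value = sim$truth$gene[seq_len(igraph::vcount(net$graph))])

report <- run_pipeline(list(expression   = sim$matrix,
                            interactions = graph_to_interactions(g),
                            n_boot = 2500, seed = 1))
report
#> pipeline_report: 148/600 DEGs (up 74, down 74); network 72 nodes / 207 edges; tree depth 5, 4 motif leaves, 12 key regulators
#> classification: scale_free = TRUE, hierarchy = strong, mixing = assortative
```

148 of the 150 planted genes pass the screen (74 up, 74 down); 72 of them
are connected above the score threshold. The decomposition tree reaches
depth 5 and terminates in 4 triangle motifs, so 12 genes (3 per motif) are
reported as key regulators — each one a member of a community at every
level of the hierarchy. The degree distribution's bootstrap p (0.49) is
above the 0.1 plausibility cut, and the dense triangle blocks give a
steeply decaying clustering profile (strong hierarchy call) with
assortative mixing.

The same chain, stage by stage with TSV outputs under `results/`, is in
the numbered drivers:

```sh
Rscript analysis/01_simulate_data.R     # expression + interaction tables
Rscript analysis/02_screen_degs.R       # DEG table
Rscript analysis/03_build_network.R     # edge list
Rscript analysis/04_topology_powerlaw.R # metrics, profiles, fits, class
Rscript analysis/05_decompose_trace.R   # tree, motifs, key regulators
Rscript analysis/06_enrichment.R        # ORA table
Rscript analysis/07_full_report.R       # consolidated JSON report
```

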
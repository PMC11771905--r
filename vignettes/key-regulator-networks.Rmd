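---
title: "Methods: key-regulator discovery in gene interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: key-regulator discovery in gene interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyregnet)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, the numerical choices made where
the design was genuinely open, and what the synthetic-data tests do and do
not demonstrate about real data.

## The problem

Complex diseases rarely trace back to a single aberrant gene; they emerge
from perturbations of an interaction network. A practical route from a
case–control expression study to candidate regulators is: screen
differentially expressed genes (DEGs), build the protein–protein
interaction (PPI) subnetwork they induce, characterize its global
architecture (scale-free? hierarchical? assortative?), decompose it into
communities at successive levels, and single out the genes that persist
through every level of that hierarchy down to the smallest cohesive unit —
a triangle, `G(3,3)`: three nodes, three edges. Those deeply rooted genes
are the *key regulators*. `keyregnet` implements that chain end to end,
with a synthetic-data module standing in for study-specific inputs.

## DEG screening

**Fold change.** Expression values are handled on the log2 scale, so the
fold change of a gene is the difference of its group means
(`case − control`); on the linear scale this equals the log2 ratio of
geometric means. Linear-scale input is accepted and transformed as
`log2(x + pseudocount)` with a default pseudocount of 1 (0 is allowed when
all values are positive). Genes with any missing value are dropped with a
warning rather than imputed.

**Moderated t-test.** With a handful of samples per group, per-gene
variance estimates are unstable. The test therefore shrinks each gene's
pooled variance `s²` (on `d = n₁ + n₂ − 2` df) toward a common prior
`s0²` with prior df `d0`:

    s²_post = (d0·s0² + d·s²) / (d0 + d),    t = Δmean / sqrt(s²_post·(1/n₁ + 1/n₂))

with two-sided p-values on `d + d0` df. The hyperparameters are estimated
by moment matching on the log sample variances: under the hierarchical
model `log s²` follows a shifted log-F distribution, so
`var(log s²) − trigamma(d/2) = trigamma(d0/2)`, inverted with a Newton
iteration, and `s0²` follows from the mean. This is the same
moment-matching idea used by the established empirical-Bayes
implementations; the test suite confirms agreement with limma's moderated
t to about 1% (the remaining gap is a finite-sample detail of the prior-df
estimator, and no bit-compatibility is claimed). `test = "ordinary"`
switches shrinkage off (`d0 = 0`), recovering the classical
pooled-variance t-test exactly — useful both as a baseline and as an
oracle hook for tests.

**Thresholds.** The screen retains genes with `|log2FC| ≥ 1` AND
`p < 0.05` AND `padj ≤ 0.05` (BH step-up). The mixed strictness
(non-strict on the fold change and adjusted p, strict on the raw p) is
deliberate and tested at the boundaries. All three cutoffs are arguments.

## Network construction

Interactions arrive as a scored pair table; the STRING export dialect
(integer scores on a 0–1000 scale) is normalized to [0, 1]. Duplicate
A–B/B–A rows collapse to their maximum score; self-pairs are dropped. The
network keeps edges with combined score strictly `> 0.4` (the
conventional medium-confidence cut; configurable) whose both endpoints
are screened DEGs. Matching is exact-string on gene symbols — identifier
mapping is out of scope and left to the caller. DEGs left without any
retained edge are excluded from the graph; their count is logged, since
the gap between "DEGs screened" and "network nodes" is part of any honest
report.

## Topological metrics

Per node: degree `k`; clustering coefficient `C = 2T/(k(k−1))` with `T`
the triangles through the node, defined 0 when `k < 2` so leaves stay in
range; neighbourhood connectivity `C_N` = mean neighbour degree (0 for
isolates); betweenness `C_B` over all shortest paths with multiplicity,
normalized by `(n−1)(n−2)/2`; closeness `C_C = (n_c − 1)/Σd` within the
node's connected component of size `n_c` (0 for singleton components);
eigenvector centrality `C_E` per component, normalized so the largest
entry is 1. Degree, clustering, neighbour degree and betweenness are
delegated to igraph (Brandes accumulation); closeness is computed from
per-component distance matrices to honour the component-wise definition;
eigenvector centrality uses the package's own power iteration (below) so
the same machinery serves centrality and community detection, with the
eigenpair residual bounded at 1e−8 in tests. The per-degree profile takes
raw arithmetic means within each observed degree bin — no log-binning,
since the profile is the object later fitted, and a log-binned variant
would change the fitted exponents silently.

**Power iteration.** The dominant eigenpair of a symmetric matrix `M` is
found by iterating on `M + σI` with `σ` = the maximum absolute row sum;
the shift makes all eigenvalues non-negative, so the algebraically
largest eigenvalue dominates and the iteration cannot oscillate on
bipartite spectra. Convergence is `‖v_{t+1} − v_t‖∞ < 1e−10` with a
10000-iteration cap. The iteration runs from two fixed start vectors —
the uniform vector and the index ramp — keeping the larger Rayleigh
quotient, because any single deterministic start can be exactly
orthogonal to the dominant eigenvector (the uniform start covers
Perron-type vectors, the ramp covers sign-structured ones). No seed is
involved: runs are reproducible by construction.

## Power-law fitting and classification

Two fitting routes serve two purposes.

**Clauset maximum likelihood (degree distribution).** The lower cutoff
`xmin` is scanned over the unique observed values, choosing the one that
minimizes the Kolmogorov–Smirnov distance between the tail empirical CDF
and the fitted law (ties go to the smallest `xmin`). The exponent is the
continuous closed form `1 + n/Σ ln(x/xmin)` or, for discrete data, the
numerical maximizer of the zeta likelihood (Hurwitz zeta via
Euler–Maclaurin summation; golden-section search on `α ∈ (1, 25]`,
agreeing with a brute-force grid to the grid step in tests). For discrete
data the KS comparison is made at the atoms against both the CDF at the
value and just below it — both step functions jump at the integers, so
this covers the whole support, including runs of unobserved values. The
goodness-of-fit p is semi-parametric bootstrap: each of `n_boot` (2500 by
convention) resamples draws body values empirically and tail values from
the fitted model, is refitted from scratch (including the `xmin` scan),
and contributes its KS distance; p is the fraction exceeding the observed
distance. A fit is called plausible when `p > 0.1` and the KS distance is
at most 0.35. The scan–refit–bootstrap loop is compiled (Rcpp) and draws
from R's RNG, so `set.seed()` makes it bit-reproducible; on tail samples
from the true model the p-value is approximately uniform (tested over 20
seeds). Discrete model draws invert a precomputed zeta CDF table (exact
to a 1e−9 far-tail cutoff, with the standard continuous approximation
beyond it).

**Log-log least squares (the five profiles).** The per-degree means of
`C`, `C_N`, `C_B`, `C_C`, `C_E` — and the degree distribution `P(k)`
itself — are fitted by OLS on `(ln k, ln y)`, keeping the slope's sign;
zero bins are dropped with a warning. Reported exponents are magnitudes
with an explicit decay/growth flag, which avoids the sign ambiguities
that creep in when decaying laws are written `k^−β` but quoted as
"negative β".

**Classification.** Hierarchy: *strong* when `C(k)` decays with magnitude
≥ 1; *weak* when it decays with magnitude < 1 while `C_N(k)` grows with
exponent in (0, 0.5]; *none* otherwise. Mixing: assortative iff the
`C_N(k)` exponent is positive. Scale-freeness is the Clauset bootstrap
decision on the degree distribution. Each call carries a human-readable
trace of which rule fired.

## Community decomposition

**The split.** A community `g` is bisected from the generalized
modularity matrix

    B_g(i,j) = A_ij − k_i k_j/2m − δ_ij Σ_{l∈g} (A_il − k_i k_l/2m)

(plain `B` when `g` is the whole graph). The leading eigenpair comes from
the shifted power iteration above; members split by eigenvector sign,
zero entries joining the positive side. The modularity gain is
`ΔQ = sᵀB_g s / 4m`, and the split is accepted only when the leading
eigenvalue and `ΔQ` are both positive (tolerance 1e−9) and both sides are
non-empty — complete graphs, for instance, are indivisible. An optional
Kernighan–Lin-style refinement (`refine = "kl"`) greedily flips the
single node with the best positive gain until no move improves `ΔQ`;
the default leaves the raw sign split untouched. The raw split is *not*
in general stable under single-node moves — refinement is exactly what
fixes that, and recovering four equal planted blocks (rather than two)
reliably requires it.

**The recursion.** The whole graph is the level-0 root "C"; children are
numbered 1..n by decreasing size (ties by smallest member symbol) and
labelled by dotted paths (`C2`, `C2.3`, `C2.3.4.1`, …). Recursion stops
at a community that is exactly a triangle (a terminal `G(3,3)` motif
leaf), has fewer than 3 members, is indivisible, or sits at `max_level`
(unbounded by default). Communities containing no triangle at all are
retained in the tree but flagged, so the tree remains auditable while
downstream key-regulator extraction consumes only motif leaves.

Two recursion scopes are provided, and the choice matters more than it
first appears. `scope = "global"` is the classical scheme: every split is
judged against the *global* modularity via `B_g`, so total Q strictly
increases down the tree — but precisely because of that stopping rule,
recursion halts at communities of roughly 6–16 nodes on every graph
family we generate, and terminal triangles are essentially never reached.
`scope = "local"` (the default) instead treats each community's induced
subgraph as a standalone network and re-applies the leading-eigenvector
method to it, the way community detection is rerun module by module in
practice; divisibility is then judged against the subgraph's own
modularity, and decomposition continues naturally down to triangle
motifs. Local scope also splits disconnected communities into their
components at any depth (global scope does so only for a disconnected
input, under a virtual root). The global-Q monotonicity property is
asserted in tests under `scope = "global"`; the motif-reaching behaviour
under `scope = "local"`. Both scopes exercise the identical split
operator.

## Key regulators

Because the tree's partitions are nested, a gene belongs to a motif leaf
if and only if it has an ancestor community at every level — "present at
every topological level" and "member of a terminal triangle" are the same
criterion, and the implementation uses the latter. The regulator count is
therefore identically 3 × (number of motif leaves); a tree with 11 motif
leaves yields 33 regulators. Each regulator is reported with its leaf
label, its two motif partners, and its network statistics (`k`, `C_B`,
`C_C`, `C`), which are required to match the topology stage bit for bit.
A `low_degree_bridge` flag marks regulators whose own degree is at most
11 while some motif partner has degree at least 17 — pure report
heuristics for surfacing the low-degree-node-next-to-hub pattern, both
configurable, chosen as the degree extremes such a report would
highlight.

## Over-representation analysis

For a query of `n` genes against a set of `K` in a universe of `N`, with
overlap `k`: the p-value is the exact hypergeometric upper tail
`P[X ≥ k]` and the fold enrichment is `(k/n)/(K/N)`. BH correction runs
across the sets of the queried collection (not across pooled
collections). The universe defaults to the analyzed network's node set —
the natural background when the query is drawn from the network — and is
configurable. Query or set members outside the universe are dropped with
a logged count. One-sided over-representation only; depletion is not
tested.

## Synthetic data: what it emulates, and what it does not

`gen_expression` emulates a small two-group study: 2000 genes by default
(600 in the worked analyses, for speed), 6 samples per group (a
12-sample design), baselines uniform on [6, 12] log2 units, gene-wise
standard deviations from a scaled inverse-chi-square prior (df 4, scale
0.09, i.e. σ around 0.3 with a heavy right tail — the regime that makes
variance moderation worthwhile), and planted effects of ±2 log2 units on
150 of 600 genes, half up and half down. `gen_graph` provides
preferential attachment (`ba`, degree exponent near 3), the deterministic
Ravasz-style `hierarchical` replication of a clique (clustering falling
roughly as 1/k — the positive control for the hierarchy classifier, with
`er` as the null), `planted_partition` for community recovery, and
`modular`: a two-scale nested block model whose bottom blocks are
triangles, used as the pipeline's network so that decomposition
exercises multiple levels and genuinely terminates in motif leaves.
`sample_powerlaw` feeds the fitter's recovery tests by inverse-CDF
sampling.

What passing these tests shows: the statistics, fits, decomposition and
tracing are implemented correctly, at their stated tolerances, on data
with the structure the method assumes. What it does not show: anything
about normalization, batch effects, RNA-seq count noise, identifier
mapping, the degree mixing of real PPI databases, or asymmetric up/down
regulation (effects are planted symmetrically; real studies skew). The
generator is a correctness instrument, not a realism claim.

## Numerical choices and degenerate inputs

- Power iteration: tolerance 1e−10, cap 10000 iterations, two fixed
  starts; eigenpair residual ≤ 1e−8 asserted in tests.
- LEV divisibility tolerance 1e−9 on both the eigenvalue and ΔQ.
- `xmin` ties → smallest value; child-order ties → smallest member
  symbol; zero eigenvector entries → positive side.
- All-equal power-law tails error ("zero log-spread"); all-zero-variance
  expression matrices error ("degenerate variance"); a gene whose case
  and control vectors coincide yields `t = 0, p = 1`; empty DEG tables,
  empty queries, and edgeless thresholds produce empty outputs or named
  errors, never silent NAs.
- Report rounding (4 decimals) applies only at the serialization
  boundary; internal tables keep full precision.
- Problem sizes in the shipped analyses: 600 genes × 12 samples, a
  75-node/5-super-community network, 2500 bootstrap resamples, 200
  random-graph oracle comparisons — sizes at which every stage's output
  can be checked against brute-force enumeration or closed forms.

## Known limitations

- The moderated test covers the two-group design only; multi-factor
  designs, batch correction and count models are out of scope.
- LEV bisection is a heuristic: it is not guaranteed to find the
  best-modularity bisection (and the tests deliberately do not assert
  that), only a sign split with non-negative gain, optionally polished
  by single-node moves.
- Community labels depend on the deterministic tie-breaks above; a
  different ordering convention would relabel (not restructure) the tree.
- The ORA engine implements the plain hypergeometric test; tools built
  around modified Fisher variants will report different p-values for the
  same overlaps.
- Closeness and eigenvector centrality are component-wise by definition;
  comparing them across components of very different sizes is not
  meaningful.
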
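# oncorewire

Network rewiring analysis of signaling across disease states, for systems
biologists studying how a *fixed* signaling topology reorganizes when only
gene expression changes. The motivating setting is colon carcinogenesis:
the same signaling network is weighted three times — with expression from
normal mucosa, adenoma, and carcinoma — and the three weighted networks
are compared globally (weight distributions, weighted diameters),
mesoscopically (overlapping modules), and at the level of individual
links and pathways. No differential-expression cutoff is applied: the
point is that reorganization is visible even without significant
per-gene fold changes.

## The model

For a typed signaling network (activating / inhibiting / undirected
links) restricted to measured genes, known link types and the giant
component:

- **Abundance.** For each state, expression matrices are
  quantile-normalized, samples are pooled, and the per-gene median of the
  normalized log2 intensities is the gene's abundance *aᵢ*.
- **Link weight.** Each link gets
  *LW(i,j) = log₁₀(aᵢ·aⱼ)* — the log product of its endpoint abundances,
  a proxy for the probability of the interaction. Weights near 1.8 are
  typical for log2 abundances near 8; links are binned as weak (< 2),
  medium ([2, 2.7]) and strong (> 2.7).
- **Diameter.** Probability-like weights become path lengths through a
  negative-log map on the product scale, *d = ln(W_max / W)* with
  *W = 10^LW*, so Dijkstra's shortest path is the most likely signaling
  route. Diameters and average path lengths are computed under three
  directivity conventions: undirected, directed (activating/inhibiting
  arcs only), and mixed (undirected links become two opposite arcs).
- **Modules.** An influence-function community landscape: decaying
  weighted spreading from every node (decay λ = 0.5) builds per-node
  influence zones; the summed zones form a height surface whose local
  maxima are module cores; assignment strengths are the row-normalized
  core zones, and hills that overlap proportionally above θ = 0.9 are
  merged. Modules overlap; each node also gets a discrete (argmax)
  assignment, and modules are named for their highest
  community-centrality member.
- **Statistics.** States are compared per edge or per gene-set member
  with an exact paired Wilcoxon signed-rank test (full permutation null
  up to n = 25, tie-corrected normal approximation above); top/bottom
  10% and 1% link strata and per-pathway medians, weighted-degree ratios
  and extreme-link counts complete the picture. All weight-derived
  results can be re-checked under ±5% multiplicative abundance noise.

A synthetic-data generator stands in for the microarray compendium: a
connected preferential-attachment network with the edge-type mix of the
Human Cancer Signaling Network (2403:741:1915:30), three expression
states sharing that topology, gene-level variance inflation in adenoma
(κ = 1.3) and a planted connected module shifted by δ = 1 (log2) in
carcinoma, with ground truth for recovery tests.

## Worked example

```r
library(oncorewire)
study <- generate_study(synthetic_config(seed = 1))
ab  <- abundance_table(lapply(study$expression, function(em)
  median_aggregate(list(quantile_normalize(em)))))
net <- filter_network(study$network, rownames(ab))
w   <- lapply(colnames(ab), function(s)
  compute_link_weights(net, ab[, s], state = s))
names(w) <- colnames(ab)

summarize_weights(w$adenoma)
#> weight_summary [adenoma]: n=1193 median=1.8086 sd=0.1662 q1=1.6864 q3=1.9087 min=1.0644 max=2.2083
#>   bins (<2 / [2,2.7] / >2.7): 0.909 / 0.091 / 0.000

paired_wilcoxon(w$normal$weights, w$adenoma$weights)$p.value
#> [1] 1.086540e-08

diameter_grid(w["adenoma"])[, c("convention", "diameter", "avg_path_length")]
#>  convention  diameter avg_path_length
#>  undirected  4.623192        2.097577
#>    directed 14.527432        5.613573
#>       mixed  6.089732        2.708628

detect_modules(w$carcinoma)
#> module_landscape [carcinoma]: 300 nodes, 10 modules (lambda=0.5, theta=0.9)
```

The adenoma state has the widest link-weight spread (sd 0.166 against
0.124 in normal) and the largest diameter under every convention — the
"least compact" intermediate state — while the per-edge weight shift
between states is highly significant despite no gene passing a fold-change
filter. The carcinoma landscape resolves ten overlapping modules named
for their organizer nodes.

The numbered scripts under `analysis/` run the full study end to end
(simulate → abundances/weights → diameters → modules → extreme links and
pathways → noise robustness), printing what each stage found and writing
its tables under `results/`.

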
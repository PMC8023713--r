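---
title: "Methods: link-weight rewiring of a fixed signaling topology"
author: "oncorewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: link-weight rewiring of a fixed signaling topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the model and its
assumptions, the parameters that matter, what the synthetic generator
does and does not emulate, the numerical conventions, and the design
choices made where the design was genuinely open.

## The model and its assumptions

The object of study is a single typed signaling network — gene-symbol
nodes joined by activating, inhibiting or undirected (association-type)
links — observed under several biological states that differ *only* in
gene expression. The analysis assumes:

1. **mRNA as a proxy for protein abundance.** Per state, each gene's
   abundance $a_i$ is the median of its quantile-normalized log2
   intensities over all pooled samples of that state. Medians are used
   because microarray intensity distributions are not normal
   (a Shapiro–Wilk screen is reported wherever gene-set medians are
   compared).
2. **Interaction probability grows with the product of endpoint
   abundances.** Each link carries
   $LW(i,j) = \log_{10}(a_i \cdot a_j)$. The product form reflects
   mass-action-like attachment of two interacting proteins; the
   logarithm tames outlying intensities. Abundances enter on the
   normalized log2 scale as stored — they are never exponentiated back —
   so with $a_i \approx 8$ typical weights sit near
   $\log_{10} 64 \approx 1.8$, which is the scale on which the
   weak/medium/strong boundaries at 2 and 2.7 are meaningful.
3. **Topology is fixed.** Every state shares one filtered network:
   links not covered by the expression data or of unknown type are
   deleted, then only the giant component (of the undirected skeleton,
   computed once before any directivity analysis) is kept. All
   differences between states are therefore attributable to expression.

## Distances and diameters

Link weights are probability-like — larger means a more likely
interaction — while shortest-path algorithms treat weights as lengths.
The package maps weights to lengths with a negative logarithm on the
*product* scale, normalized by the state's maximum:
$$d_e = \ln\!\frac{W_{\max}}{W_e}, \qquad W_e = 10^{LW_e}.$$
Three properties motivated this exact form:

- $d_e \ge 0$ with equality at the most likely link, so Dijkstra is
  applicable and the shortest path is the most likely transition path;
- rescaling all abundances by a common factor multiplies every $W_e$
  and $W_{\max}$ alike and leaves every distance unchanged (a
  conservation property that makes cross-state comparisons meaningful
  even if normalization shifts the global intensity level);
- summed along a typical ten-hop path it reproduces the magnitude of
  weighted diameters reported for networks of this kind.

A sum-normalized variant (`"neglog-sumnorm"`, $W_{\max} \to \sum_e W_e$)
is available; it makes $e^{-d}$ a proper probability over links and is
insensitive to the single largest weight, but produces much larger
absolute path lengths. Max-normalization is the default. Its known
limitation: the whole distance scale of a state hangs on one extremal
link, so a localized change that creates a new maximum weight lengthens
every *other* distance in that state. Cross-state diameter comparisons
should be read with this in mind (see *Limitations*).

Directivity is handled three ways: **undirected** (all links, both
directions), **directed** (only activating/inhibiting arcs, original
orientation), and **mixed** (directed arcs plus each undirected link as
two opposite arcs of equal distance). The undirected view is restricted
to its largest connected component and the directed/mixed views to their
largest strongly connected component — the choice made where "removing
the isolated parts" is otherwise ambiguous — so every reported pair is
reachable. Shortest distances between members of a strongly connected
component never need nodes outside it, so the restriction is exact, and
because the three arc sets are nested (directed ⊂ mixed ⊂ undirected,
with the same per-arc distances from the shared $W_{\max}$), distances
nest the opposite way for every commonly reachable pair. Parallel arcs
between a pair keep the minimum distance; directed and mixed views
average over ordered pairs, the undirected view equivalently over
unordered ones. The diametral pair is made deterministic by taking the
lexicographically smallest (source, target) among ties.

## The community landscape

Overlapping modules are detected with a self-contained influence-function
algorithm in the spirit of landscape-based community analysis:

- **Spreading.** From a seed node carrying influence 1, each node passes
  $\lambda$ times its current increment to its neighbors in proportion
  to incident link weights (row-normalized), synchronously, until the
  total increment drops below $\varepsilon$. The accumulated vector is
  the seed's *influence zone*; with $\lambda = 0.5$ (default) a zone's
  total mass is $1/(1-\lambda) = 2$ and its reach decays by half per
  step, giving zones a 2–4-hop horizon — local enough to resolve
  protein-complex-sized modules, broad enough to overlap.
  $\varepsilon = 10^{-6}$ trades a $\sim 20$-iteration cost against
  truncation error far below assignment differences that matter.
- **Hills.** The landscape height $h(n)$ is the summed influence $n$
  receives from all zones. Module cores are the local maxima
  ($h \ge$ all neighbors); the assignment strength of node $n$ to core
  $c$ is the core's influence at $n$, normalized per node to sum to 1.
- **Merging.** Two hills are one module when their zones coincide. The
  proportional overlap of two zones is the sum of coordinate-wise minima
  relative to the smaller zone's mass, evaluated *outside the
  constituent core nodes of both hills* — after a merge the combined
  hill's mass sits on several cores, and excluding them keeps the
  measure about shared periphery rather than core idiosyncrasy (a
  uniform clique, where every node is a core, then correctly collapses
  to a single module, while two cliques bridged by a weak link stay
  separate). Hills merge iteratively, highest overlap first, while any
  overlap exceeds $\theta = 0.9$; the surviving core is the higher one.
- **Outputs.** Discrete assignment is the per-node argmax (ties to the
  lexicographically smallest module id). *Community centrality* is the
  landscape height — the whole network's influence on a node — and
  modules are named for their highest-centrality discrete member, the
  module's organizer. This "received influence" definition is the one
  that ranks a star's center above its leaves and gives an isolated
  node centrality 1; the alternative "exerted influence" reading is
  degenerate under mass-conserving spreading (every non-isolated node
  would exert exactly $1/(1-\lambda)$). Where the literature names but
  does not define *modular overlap* and *effective degree*, the package
  uses the exponential Shannon entropy of the assignment row (the
  effective number of modules a node belongs to) and the weighted
  degree (sum of incident link weights).

Determinism: iteration orders are fixed by sorted node symbols, all
tie-breaks are lexicographic, and spreading is synchronous, so identical
inputs give identical landscapes on any platform. Nodes beyond the
truncation horizon of every core (possible on very elongated graphs)
fall back to the hop-nearest core. Cross-state module matching sends
each module to the module of the other state receiving the plurality of
its discrete members, reports the Jaccard similarity of the member sets,
and annotates many-to-one patterns as merges and one-to-many as splits.

## Statistics

State comparisons use a paired Wilcoxon signed-rank test implemented in
the package: zero differences are dropped, ranks are mid-ranks, and for
$n \le 25$ the two-sided p-value comes from the exact permutation null
(a generating-function count over doubled mid-ranks, so ties are exact
too); above 25 a tie-corrected normal approximation with continuity
correction is used. The standard library test was not suitable as the
primary route because its exact branch disables under ties; it serves
as an independent cross-check in tie-free cases. Gene-set tests pair by
gene and require at least 5 in-network members; degenerate all-zero
pairings are reported as not-computed rather than fabricated.

Extreme-link strata take the top/bottom $\lfloor 0.10E \rfloor$ links
and, nested inside, the top/bottom $\lfloor 0.01E \rfloor$; boundary
ties are broken by (weight, source, target) order so strata are
reproducible. A link belongs to a module only when *both* endpoints are
discretely assigned to it (overlap-spanning links count for neither);
a link is pathway-associated when *at least one* endpoint is a member
(a both-endpoints mode is available).

## What the synthetic generator emulates — and what it does not

The generator reproduces the *statistical shape* the analysis assumes:

- a connected typed network (default 300 nodes, 1200 links) grown as a
  preferential-attachment tree densified with uniform random links, with
  the edge-type mix allocated exactly (largest-remainder rounding of
  2403:741:1915:30);
- log2-scale abundances centered near 8 (baseline sd 1.5, truncated
  above 0.5), with per-sample noise of sd 0.5 — a typical within-state
  log2 variability for microarray intensities — and 50 samples per
  state;
- three states sharing topology: adenoma inflates gene-level deviations
  from the grand mean by κ = 1.3 (so per-state medians, and hence the
  link-weight spread, inherit the inflation); carcinoma adds δ = 1 to a
  planted connected module of 30 genes chosen breadth-first from the
  top-degree hub;
- gene sets: the planted module plus size-matched random decoys, with a
  ground-truth record for recovery tests.

It deliberately does **not** emulate probe-level effects, batch or
series structure, gene–gene expression correlation, or — importantly —
*topological* community structure: the planted module exists in the
expression effect only, not as a denser subgraph. Passing tests on this
generator therefore certify the pipeline's mechanics (weights,
distances, landscapes, statistics, determinism) and the qualitative
adenoma-dispersion signature; they do not certify that a
weakly-expressed effect of this size is recoverable as a module, nor
how the method behaves under real microarray artifacts.

## Numerical conventions and degenerate inputs

Quartiles use linear interpolation between order statistics (the
default quantile definition), bins are weak $<$ 2, medium $[2, 2.7]$,
strong $>$ 2.7. Probe collapsing and duplicate-gene rows use
element-wise medians; duplicate same-type links merge while
different-type parallels are kept. Empty filtering results, single
samples, all-zero pairings, empty modules and isolated seeds each have
a defined behavior (error, warning + pass-through, not-computed flag,
drop + warning, self-only zone, respectively) rather than silent
propagation. One master seed drives everything; stages derive their own
seeds by fixed offsets so each stage is independently reproducible, and
the ±5% noise check multiplies every abundance by exactly 0.95 or 1.05
with probability one half.

The shipped tests exercise the shortest-path machinery against a
Floyd–Warshall oracle on graphs up to 50 nodes, the signed-rank test
against full $2^n$ enumeration up to $n = 12$, and the full study at
the default 300-node configuration over ten seeds — sizes chosen so the
whole suite settles in well under a minute while still covering every
convention and tie case.

## Known limitations

- **Max-normalized distances couple states through one link.** A
  boosted region that happens to contain a state's new maximum-weight
  link lengthens all other distances in that state, which can offset or
  invert small cross-state diameter differences. The sum-normalized map
  avoids this at the cost of a different absolute scale.
- **Expression-only modules are weakly identifiable.** A +1 log2 shift
  moves a link weight by only ~0.05 of ~1.8 (≈3%), below the weight
  variation induced by the baseline spread of abundances; and a
  breadth-first ball around a hub is partly an arbitrary traversal
  choice. Recovery of such a planted module from the landscape is
  therefore intrinsically partial — a property of the study design this
  benchmark makes explicit, not of any particular detection algorithm.
- **No batch correction.** Pooling samples across series after quantile
  normalization assumes series-comparable distributions; systematic
  series effects would propagate into abundances.
- The landscape algorithm is a self-contained method in the spirit of
  influence-function community detection; numeric parity with any
  particular external implementation is not a goal.
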
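---
title: "Haplotype connectivity: scoring hot-spots and melting-pots of genetic diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype connectivity: scoring hot-spots and melting-pots of genetic diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapconn)
```

## The problem

A geographic region that harbours unusually high intraspecific genetic
diversity can have come by it in two very different ways.  It may be a
**hot-spot** (refugium): a region where the species persisted and
diversified in situ over long periods, leaving haplotypes spread more or
less evenly across the haplotype phylogeny.  Or it may be a
**melting-pot**: a zone of secondary contact where gene pools that
diverged in isolation have recently mixed, leaving haplotypes clumped
into a few divergent clusters.  Classical diversity measures cannot tell
these apart -- two phylogenies with identical total length can carry
either signature -- yet the distinction matters both in phylogeography
(identifying refugia) and in conservation planning.

`hapconn` quantifies the difference through **haplotype connectivity**:
a region whose haplotypes can be linked by chains of small mutational
steps scores low (hot-spot-like); a region whose haplotypes sit in
divergent clusters that can only be linked by crossing a large gap
scores high (melting-pot-like).

## The model

All computations start from a set $X$ of haplotypes and a symmetric
dissimilarity $D$ with zero diagonal: Hamming distances between aligned
sequences, summed absolute allele-size differences for microsatellite
profiles, or phyletic (path-length) distances along a haplotype
phylogeny or network.  No triangle inequality is assumed anywhere.

For a subset $Y \subseteq X$ (the haplotypes found in one region) and a
threshold $t \ge 0$, the *threshold graph* $G_t(Y)$ joins two distinct
haplotypes whenever $D(x, y) \le t$ (inclusive comparison).  The
**haplotype connectivity** is

$$HC(Y) = \min \{\, t \ge 0 : G_t(Y) \text{ is connected} \,\}.$$

$HC$ coincides with the *bottleneck* value of a minimum spanning tree of
the complete weighted graph on $Y$: every MST minimises its maximum edge
weight, so `haplotype_connectivity()` simply runs Prim's algorithm
($O(|Y|^2)$ on the complete graph) and reports the largest tree edge.
Consequences used throughout: $HC(\{x\}) = 0$, and for $|Y| \ge 2$ the
value always equals some entry $D(x, y)$ -- on integer-valued inputs all
results are exact integers.

### Sample-size normalization

Raw $HC$ values of differently sized regions are not comparable, so each
is normalized against the extremes attainable by *any* subset of the
same size $k$ drawn from the full haplotype set:

$$HC^*(Y) = \frac{HC(Y) - HC_{\min}(k)}{HC_{\max}(k) - HC_{\min}(k)},
\qquad k = |Y|,$$

which always lies in $[0, 1]$ (defined as 0 when the range is
degenerate, e.g. when one region contains every haplotype).

* $HC_{\min}(k)$ (the bottleneck $k$-MST value) is found by a single
  Kruskal-style union-find sweep: it is the first threshold at which a
  connected component of $G_t(X)$ reaches $k$ vertices, because a
  spanning tree of such a component can be pruned to any $k$ of its
  vertices.
* $HC_{\max}(k)$ uses the vertex-separator characterisation: every
  $k$-subset is connected at level $t$ iff $G_t(X)$ is connected and its
  vertex connectivity $\kappa$ exceeds $|X| - k$ (Menger's theorem;
  $\kappa$ of a complete graph is $|X| - 1$ by convention).  The package
  binary-searches the sorted distinct distances, computing $\kappa$ by
  max-flow (igraph).  Because the condition $\kappa > |X| - k$ relaxes
  as $k$ grows, $HC_{\max}$ is non-increasing for $k \ge 2$, while
  $HC_{\min}$ is non-decreasing -- both facts are property-tested
  against exhaustive enumeration.

`connectivity_bounds()` computes both extrema for many $k$ at once,
re-using the sorted distances, the union-find sweep and the cached
per-threshold $\kappa$ values.

### Diversity companions

Connectivity is only interpretable for regions that are diverse in the
first place, so the same raw/min/max/normalized treatment is applied to
a diversity measure:

* **PD** (phylogenetic diversity), when a tree phylogeny is available:
  the total length of the smallest subtree spanning the region's
  haplotypes.  Labels may sit on interior vertices (haplotype
  phylogenies routinely place sampled haplotypes at interior nodes), so
  the subtree is the Steiner tree of the labelled vertex set.
  $PD_{\max}(k)$ uses the greedy chain that is provably optimal for PD
  maximisation; $PD_{\min}(k)$ uses the i-tree dynamic programme over
  the rooted tree, taking the minimum over all subtrees covering at
  least $k$ labelled vertices.
* **AD**, when only a distance matrix is available: the average squared
  pairwise distance (exponent 2 by default; the unsquared variant is
  exposed via `exponent = 1` because conventions differ between
  sources and the two orderings can disagree).  Its $k$-subset extrema
  are NP-hard (MAXISUM dispersion), so `ad_extrema()` is exact-only:
  exhaustive enumeration below 16 haplotypes, a branch and bound with
  pairwise-sum bounds up to a default cap of 25, and a capacity error
  above that -- never a silent approximation.

The **genetic diversity spectrum** (`gds()`) -- the histogram of
pairwise distances -- is provided as a complementary diagnostic:
bimodality suggests two divergent clusters.

### Scoring and interpretation

`score_regions()` assembles one row per region (size, raw/min/max/
normalized diversity and connectivity), with extrema computed over the
*full* haplotype set at each region's size and cached per distinct size;
rows are ordered by normalized diversity (ties broken by region name).
`interpret_regions()` adds an advisory annotation: among regions at or
above the median normalized diversity (quantile configurable), those
with $HC^* \ge 0.5$ (cut configurable) are flagged melting-pot-like, the
rest hot-spot-like; low-diversity regions are explicitly *not assessed*,
because low diversity forces low connectivity and the signal carries no
information there.  The cuts are conventions for ranking and flagging,
not significance tests; conclusions should be drawn comparatively, as in
the published case studies.

## Worked example

The two packaged toy phylogenies make the contrast concrete.  Both have
13 sampled haplotypes on unit-edge trees of total length 16, so PD for
the full sets is identical -- yet:

```{r}
D_hot  <- phyletic_distances(toy_phylogeny("hot_spot"))
D_melt <- phyletic_distances(toy_phylogeny("melting_pot"))
c(hot_spot = haplotype_connectivity(D_hot),
  melting_pot = haplotype_connectivity(D_melt))
```

In the melting-pot tree even a thinned subset keeps the signature, since
any chain between the two haplotype groups must cross the unsampled
bridge:

```{r}
Y <- paste0("b", seq(2, 12, by = 2))
haplotype_connectivity(D_melt, Y)
igraph::is_connected(threshold_graph(D_melt, Y, t = 2))
```

## The synthetic scenario generator

`simulate_scenario()` produces the structures the score is designed to
distinguish, for tests and power exploration:

* *hot_spot*: one random unit-edge tree grown by sequential uniform
  attachment, with the sampled haplotypes placed uniformly over its
  vertices;
* *melting_pot*: two (or more) such trees joined by a path of
  unlabelled vertices of length `separation` (mimicking extinct or
  unsampled intermediates), with sampled haplotypes confined to the
  clusters and the focal region stratified across them.

Defaults -- 12 sampled haplotypes on 30 vertices, 2 clusters, separation
10, focal region of 6 -- were chosen once as a small but realistic
intraspecific sampling scheme: the separation clearly exceeds the
typical within-cluster spread of a 10-vertex random attachment tree
(depth of order $\log n$), which is precisely the regime in which
secondary contact is diagnosable at all.  Matching `n_vertices` across
scenarios matches total tree length, so raw PD distributions overlap and
any discrimination is attributable to connectivity.  Over 50 seeds per
scenario the mean normalized connectivity of melting-pot focal regions
is markedly higher than for hot-spot regions (about 0.78 vs 0.47 under
the defaults) -- this is asserted, not assumed, in the test suite.

What the generator does *not* emulate: coalescent genealogies, mutation
rate heterogeneity, geographic sampling bias, haplotype frequencies
(the scores deliberately ignore multiplicities), or missing data.
Passing simulation tests therefore show that the scores separate the two
idealised topological signatures, not that they are robust to every
real-data complication.

## Numerical choices and degenerate cases

* Threshold comparison is inclusive ($D \le t$) and exact as stored --
  no epsilon: every candidate threshold is one of the matrix entries
  (or 0), so on integer inputs all HC-family results are integers.
* $HC$ of an empty set is an error; singletons give 0; duplicate
  haplotypes at distance 0 are permitted.
* Normalization of a degenerate range ($\mathrm{lo} = \mathrm{hi}$)
  returns 0; raw values outside $[\mathrm{lo}, \mathrm{hi}]$ raise an
  invariant-violation error rather than clamping silently.
* Display rounding is 2 decimals, half-up (matching conventional score
  tables); machine-readable output (JSON) keeps full precision.
* PD requires a tree; cyclic haplotype networks are accepted for
  phyletic distances (shortest paths) but rejected by `pd()`.
  Phyletic distance sums edge lengths; edge counts are the unit-length
  special case.  Missing Newick branch lengths default to 1 with a
  warning.
* Hamming distances use pairwise deletion of gap/ambiguity columns by
  default (`count_gaps = TRUE` scores them), the least destructive
  convention for alignments of haplotypes.

## Validation strategy and problem sizes

Every optimisation routine is tested against an independent oracle:
threshold-scan connectivity for $HC$; exhaustive enumeration over all
$k$-subsets for $HC_{\min}/HC_{\max}$ (200 random matrices up to 9
haplotypes, every $k$), for $PD_{\min}/PD_{\max}$ (100 random partially
labelled trees up to 10 labels, every $k$, via an edge-bipartition
oracle), and for the AD branch and bound (10 random matrices of 10
haplotypes).  These sizes make exhaustive enumeration itself cheap and
trustworthy while exercising ties, duplicate distances and degenerate
topologies; the algorithms contain no size-dependent branches, so small-
$n$ equivalence is informative about behaviour at realistic scale.

## Limitations

* $HC_{\max}$ needs repeated vertex-connectivity computations; for very
  large haplotype sets (many hundreds) this dominates runtime.
* AD extrema are exact-only and capped (NP-hard); no heuristic fallback
  is offered.
* No statistical significance is attached to the scores; the extremal
  normalization is a first step toward the subset distribution of $HC$,
  not a null model.
* Geographic side-constraints on subsets (e.g. restricting the extrema
  to geographically plausible subsets) are not implemented.
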
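---
title: "Seed-expanded molecular maps and network proximity analysis with cellmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seed-expanded molecular maps and network proximity analysis with cellmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(cellmapr)
```

## The analysis in one paragraph

cellmapr implements a network-medicine workflow for relating a physiological
or metabolic state to a disease at the molecular level. The state is
represented by a *condition map*: starting from a curated list of *seed
proteins* (the molecules known to drive the state, e.g. the enzymes of the
pathways it engages), the map is grown by recursively incorporating all known
relationships of the current proteins from a typed protein-relationship
universe (physical interactions, metabolic couplings, signalling links). The
disease is represented by its *effector proteins* — the proteins a curated
condition database holds finally responsible for its phenotype, grouped into
pathophysiological *motives* (sub-mechanisms such as insulin resistance).
Three complementary questions are then asked of the map: **presence** (what
fraction of the disease's effectors the map contains), **proximity** (how
many network jumps separate the effector set from the seed set, judged
against an empirical null of all condition-pair distances), and
**clustering** (where the effectors concentrate on a 2D geodesic projection
of the map). A protein-level pass enumerates the direct and short-range
links behind any observed proximity.

## Distances between protein sets

The unit of distance is the *jump*: one edge traversal in the undirected,
unweighted view of the map. For protein sets $A$ and $B$ inside the map's
largest connected component, the package computes the directed minima
$d(a, B) = \min_{b \in B} d(a, b)$ for every $a \in A$ and vice versa, and
aggregates them symmetrically:

* **pooled mean** — $\frac{1}{|A|+|B|}\left(\sum_{a} d(a,B) + \sum_{b} d(b,A)\right)$,
  the headline statistic;
* **mean of means** — $\frac{1}{2}\left(\overline{d(a,B)} + \overline{d(b,A)}\right)$,
  which weights both directions equally regardless of set size;
* **minimum pairwise distance** — an integer, reported alongside;
* the classical max–min Hausdorff distance, as a diagnostic only.

This average-minimum form is the *modified* Hausdorff distance commonly used
for point-set comparison; the classical max–min form is dominated by single
outliers and is not the quantity of interest here. Proteins absent from the
map, or outside its largest component, are dropped and counted rather than
assigned an arbitrary penalty distance: the comparison is between the
represented parts of each set.

Significance is empirical. `null_distribution()` computes the chosen
statistic for every unordered pair of conditions in the database
($\binom{k}{2}$ comparisons for $k$ usable conditions) and
`percentile_of()` reports the closed empirical CDF $P(X \le d)$. A normal
fit (mean, sd) is reported for descriptive comparison only — the decision
quantity is the distribution-free percentile. A second reference mode
(`versus =`) compares one fixed set (typically the seed set or one source
pathway) against every condition, which is the natural reference when the
question is "which conditions are unusually close to *this* set".

### Choosing between pooled mean and mean of means

Both readings of "the average number of jumps between each protein in one
set against the closest proteins in the other, and vice versa" are exposed.
They differ materially when set sizes are very unequal: against a seed set
of several hundred proteins, a 20-effector condition contributes only ~5% of
the pooled directed minima, so the pooled mean is dominated by the seed
side and can dilute a genuine proximity signal carried by the effectors.
For condition-pair nulls (sets of comparable size) the pooled mean is the
default; for seed-set-versus-condition screens, including the planted-signal
recovery experiments below, the package uses the mean of means, which gives
the effector side equal weight. Reports always label the statistic used.

## Map construction

`build_map(seeds, store, depth)` returns the induced subgraph of the
universe on all proteins within `depth` jumps of any seed — *induced*
meaning every universe edge among the included proteins is kept, not just
the expansion tree. Published seed-expanded maps are far denser than trees
(tens of thousands of relationships over a few thousand proteins), which is
only consistent with induced closure. The recursion depth is exposed rather
than fixed: one step of expansion around a few hundred seeds on a realistic
universe already grows the map roughly eight-fold, and
`expansion_profile()` tabulates node/edge counts per depth so users can
calibrate against an intended map size. Seeds missing from the universe are
retained as isolated nodes (with a warning) so presence statistics against
the full seed list remain well defined. Distances are always computed on
the undirected view: jump counts averaged "and vice versa" are symmetric
quantities, and physical interactions carry no orientation; any direction
metadata in the input is preserved but unused.

## Presence analysis and the floor convention

`presence()` reports $n_{\text{present}} / n_{\text{total}}$ with the
percentage computed as $\lfloor 100\, n_{\text{present}} / n_{\text{total}}
\rfloor$. The floor convention is deliberate: presence fractions like 19/52
(36.54%) and 13/23 (56.52%) are conventionally reported as 36% and 56% in
this literature, which nearest-integer rounding would contradict (37%, 57%).
The same convention is used for per-motive link percentages.

## 2D projection and density clustering

`geodesic_mds()` computes all-pairs jump distances on the largest component
and applies classical (Torgerson) multidimensional scaling — double
centering of the squared distance matrix followed by the top-2
eigenvectors, i.e. the Isomap construction on geodesic distances. Classical
MDS was chosen over iterative stress majorisation because it is fully
deterministic: no initialisation, no convergence tolerance, no run-to-run
variation. Orientation ambiguity (each eigenvector is defined up to sign)
is resolved by a fixed convention: each axis is flipped so the coordinate
of the lexicographically smallest protein id (compared in the C locale) is
nonnegative. An iterative refinement is available as `method = "sammon"`
(Sammon mapping started from the classical solution, hence also
deterministic) for users who want local distance preservation emphasised;
the classical solution remains the default and the reference.
`distance_preservation()` quantifies the projection quality as the Spearman
correlation between jump and embedded distances over a seeded pair sample;
on exactly embeddable metrics (paths) it is 1 up to ties.

`density_grid()` rasterises an embedding into proteins-per-cell counts
(exact mass conservation, half-open cells with the final edges closed) or
an isotropic Gaussian KDE evaluated at cell centres with Scott's-rule
bandwidth $h = n^{-1/6}\sqrt{(\mathrm{var}\,x + \mathrm{var}\,y)/2}$ by
default. Both the grid resolution (default $256 \times 256$) and the
bandwidth are recorded in the result, since neither is canonical. All grids
of one analysis share the full embedding's 5%-padded bounding box, so a
condition overlay and the map background are cell-commensurable, which is
what makes overlay images and motive-by-motive comparisons meaningful.
`peak_regions()` thresholds a grid at a quantile of its positive cells and
returns 4-connected components ordered by contained mass — the numeric
counterpart of "the cluster of condition X sits here".

## Protein-level links

`direct_links()` enumerates the edges of the seed–effector cut (one
protein may establish several relations; a protein in both sets
contributes through each qualifying incident edge), and `k_jump_links()`
generalises to all distinct-protein pairs within `k` jumps, annotated with
their distance. The default radius is `k = 2`, matching the working notion
of "functionally adjacent" used when interpreting such maps; the radius is
configurable and always reported, since a total relationship count is only
meaningful relative to it. `motive_breakdown()` attributes direct links to
motives once per motive of the effector, flagging multi-motive counting.

## The synthetic-data module

Curated condition databases and historical interaction snapshots are
proprietary, so the package ships generators that emulate their
statistical structure rather than their content:

* `generate_universe()` — a connected preferential-attachment graph
  (heavy-tailed degrees, as in real interactomes), each edge typed from a
  configurable mix of interactome/metabolome/signalling; an Erdős–Rényi
  variant exists for oracle-friendly tests.
* `generate_condition_db()` — conditions with 1–3 motives and tens of
  effectors drawn uniformly from the universe; optionally one *planted*
  condition whose effectors are sampled from the proteins exactly one jump
  from a target seed set (excluding the seeds, so presence and distance
  signals stay distinguishable).
* `generate_fixture_bundle()` — writes universe (SIF), seed list,
  condition GMT and a checksummed manifest at two scales. The `small`
  scale (300 proteins, 30 seeds, 12 conditions) drives the fast tests.
  The `paper_like` scale uses a 20,000-protein universe with attachment 4,
  447 seeds and 161 conditions: under depth-1 expansion this yields maps
  of roughly 3,000–4,000 proteins across generator seeds, the size class
  of a published seed-expanded interaction map. The attachment parameter
  was calibrated once against that target band and then fixed.

What the generator does *not* emulate: biological modularity (pathway
co-membership, complexes), edge-type correlations, study bias in curated
interactomes, or overlapping effector sets between related diseases.
Passing tests therefore demonstrate correctness of the computations and
recoverability of topological signal under a realistic degree
distribution — not biological validity of any particular map.

### Planted-signal recovery, and where it is measured

The recovery experiment asks: if a condition's effectors truly sit one jump
from the seed set, does the pipeline flag it? The package measures this on
the **universe graph**, comparing each condition's seed-set distance (mean
of means) against the seed-versus-all-conditions distribution. It is *not*
measured inside a depth-1 map, for a structural reason: a depth-1 map
contains, by construction, only proteins within one jump of the seeds, so
after restriction to the map every condition's surviving effectors look
"planted" and distance percentiles lose their contrast — inside such a map
it is the presence percentage (100% for the planted condition versus ~17%
for random ones at the realistic scale) that discriminates. Under the study
conditions used in the test suite (2,000-protein universe, attachment 3,
100 target seeds, 160 conditions of 10–30 effectors, 20 replicate seeds)
the planted condition attains a percentile ≤ 0.05 in every replicate while
the non-planted percentiles are consistent with uniformity
(Kolmogorov–Smirnov test).

## Numerical and degenerate-input choices

* Self-loops are dropped at ingest (they cannot change any jump distance);
  parallel edge records merge with the union of their type sets; all edges
  have unit length regardless of type.
* Component ties in `largest_component()` break toward the component
  containing the lexicographically smallest id; all lexicographic
  comparisons use C-locale radix ordering so results do not depend on the
  session locale.
* An embedding of $n < 3$ points pads missing MDS axes with zeros; a
  degenerate spectrum is handled by the sign convention, never by
  randomness.
* Empty sets, sets with no in-map representative, infeasible plantings,
  malformed database lines and unknown relationship types abort with
  specific messages; conditions with no in-map effectors are skipped from
  nulls with a warning, and the comparison count is always exactly
  $\binom{k}{2}$ for the $k$ conditions used.
* Percentiles use the closed comparison $P(X \le d)$; with $k$ usable
  conditions the smallest attainable seed-reference percentile is $1/k$.

## Worked example at small scale

```{r example, eval = FALSE}
fx <- generate_fixture_bundle(tempfile("demo"), scale = "small", seed = 4)
universe <- read_sif(fx$universe)
seeds <- read_seed_list(fx$seeds)
db <- read_conditions(fx$conditions)

map <- build_map(seeds, universe, depth = 1)
map_summary(map)

presence_report(map, db)                     # planted condition: 100%
d <- set_distance(map, map_seeds(map), effectors(db, "planted_condition"))
nd <- null_distribution(map, db)             # all condition pairs
percentile_of(nd, d$pooled_mean)

emb <- geodesic_mds(map)
ov <- cluster_overlay(emb, emb$coords$id, effectors(db, "planted_condition"),
                      resolution = c(64, 64), mode = "kde")
peak_regions(ov$overlay, 0.9)
```

The full pipeline (`run_analysis()`) chains these stages from one
configuration, re-reading each stage's artifact from disk so stages can be
rerun in isolation, and writes a manifest with every setting in force.

## Problem sizes used by the tests

The suite exercises the realistic (`paper_like`) scale once — the
end-to-end determinism check runs the whole pipeline twice on a
~3,500-protein map and compares outputs byte for byte — and otherwise works
at small scales chosen for tight oracle checks: exhaustive Floyd–Warshall
comparisons on 100 random graphs of up to 50 nodes, a 161-condition null
(12,880 pairs) on a 1,200-protein universe recomputed by naive double loop,
and the 20-replicate recovery experiment described above.

## Known limitations

* The distance machinery treats all relationship types identically; there
  is no support for confidence weights or directed signalling logic.
* Classical MDS of a large map concentrates hub-adjacent proteins near the
  origin; stress is reported, but for maps whose geodesic metric is far
  from 2D-embeddable the projection (and hence density clustering) is a
  coarse summary.
* The empirical null inherits whatever biases the condition database has;
  with few usable conditions the percentile resolution is limited to
  $1/\binom{k}{2}$.
* Generated universes are connected by construction; real snapshots need
  `largest_component()`, which the analysis functions apply themselves.
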
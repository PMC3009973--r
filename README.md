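# cellmapr

Seed-based molecular map construction and network proximity analysis.

## What problem this package addresses

Network medicine asks whether two physiological states — say, a metabolic
state induced by a diet and a disease — share molecular machinery, by
placing both on a protein-relationship network and measuring their
topological relationship. cellmapr implements that workflow end to end for
analysts who have:

* a **relationship universe**: a typed protein–protein edge list (physical
  interactions, metabolic couplings, signalling links) in SIF, GraphML or
  3-column TSV;
* a **seed list**: the proteins known to drive the state of interest, one
  accession per line;
* a **condition database**: conditions mapped to their *effector proteins*
  (the proteins finally responsible for each phenotype), grouped into
  pathophysiological *motives*, in GMT or long TSV.

From these it builds the state's *condition map* — the induced subgraph of
the universe on all proteins within a configurable number of jumps of any
seed — and runs four analyses against any condition in the database.

## The statistics at the core

With jump distance $d(u,v)$ = minimum edge count between proteins (computed
on the undirected map), the distance between protein sets $A$ and $B$ is the
average-minimum (modified Hausdorff) form built from the directed minima
$d(a,B)=\min_{b\in B} d(a,b)$:

$$
D_{\mathrm{pooled}}(A,B) \;=\; \frac{\sum_{a\in A} d(a,B) + \sum_{b\in B} d(b,A)}{|A|+|B|},
\qquad
D_{\mathrm{mom}}(A,B) \;=\; \frac{\overline{d(a,B)} + \overline{d(b,A)}}{2},
$$

with the minimum pairwise distance and the classical max–min Hausdorff
reported alongside. Significance is empirical: the observed distance is
ranked within the distribution of the same statistic over all
$\binom{k}{2}$ condition pairs of the database (or over all
seed-versus-condition comparisons), and the closed ECDF percentile
$P(X \le d)$ is reported. Presence is $\lfloor 100\,n_{present}/n_{total}\rfloor$
percent of a condition's effectors contained in the map. Clustering works
on a 2D classical-MDS projection of the geodesic distances (the Isomap
construction) through shared-extent density grids and their high-density
connected regions. A protein-level pass enumerates direct (1-jump) and
$\le k$-jump seed–effector relationships with per-motive breakdowns.

A synthetic-data module generates preferential-attachment universes, seed
lists and condition databases — optionally with one condition *planted* one
jump from the seeds as a positive control — so the whole pipeline is
testable without proprietary interaction snapshots.

## Worked example

```r
library(cellmapr)

fx <- generate_fixture_bundle(tempfile("demo"), scale = "small", seed = 4)
universe <- read_sif(fx$universe)
seeds    <- read_seed_list(fx$seeds)
db       <- read_conditions(fx$conditions)

map <- build_map(seeds, universe, depth = 1)
map_summary(map)
#> # A tibble: 1 × 8
#>   name          n_nodes n_edges n_seeds deg_q1 deg_median deg_q3 n_components
#> 1 condition_map     119     185      30      2          2      4            1

head(presence_report(map, db), 4)
#>   condition n_total n_present   pct
#> 1 C001            8         3    37
#> 2 C002            4         1    25
#> 3 C003            8         1    12
#> 4 C004            8         2    25

d <- set_distance(map, map_seeds(map), effectors(db, "planted_condition"))
d
#> <set_distance> pooled_mean 2.000 | mean_of_means 1.633 | min 1 jumps (|A|=30, |B|=8, 0 dropped)

nd <- null_distribution(map, db)      # all condition pairs
nd
#> <null_distribution> pooled_mean over 66 comparisons: mean 3.045 jumps, sd 0.726

percentile_of(nd, d$pooled_mean)
#> # A tibble: 1 × 3
#>       d percentile normal_percentile
#> 1     2     0.0606            0.0749
```

Reading: the depth-1 map around the 30 seeds holds 119 proteins and 185
relationships. The planted condition sits 2.0 jumps (pooled mean) from the
seed set, whereas a typical pair of conditions in this 12-condition database
is 3.0 ± 0.7 jumps apart; only ~6% of condition pairs are as close — the
planted topological proximity is recovered. `geodesic_mds()`,
`density_grid()`/`cluster_overlay()`/`peak_regions()` and
`direct_links()`/`k_jump_links()` continue the analysis at the image and
protein levels, and `run_analysis()` chains everything from one (YAML)
configuration with a deterministic, manifest-documented output bundle.
`tidy()`/`glance()` methods return tibbles for every result type, and
`autoplot()` draws embeddings, density grids and null distributions. A thin
command-line wrapper lives in `inst/scripts/cellmap.R`.

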
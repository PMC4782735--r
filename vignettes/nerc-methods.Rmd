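---
title: "Relational clustering of assemblage data: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relational clustering of assemblage data: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nerclust)
```

## The problem

Biogeographic studies of species occurrence data — fossil assemblages in
particular — routinely ask whether localities fall into distinct faunal
regions. The data arrive as a species × site matrix of specimen counts or
presences, are converted to a pairwise dissimilarity matrix with an
ecological index, and are then clustered. Most of the indices in common use
(Sørensen among them) are not Euclidean, and the regional structure in
occurrence data is reticulate rather than tree-like, so the standard
hierarchical tools (single/complete linkage, UPGMA) sit uneasily on this
problem: a dendrogram imposes a nested one-to-many history, and cutting it
into discrete groups is notoriously sensitive to outlying sites.

`nerclust` implements a non-hierarchical, non-Euclidean alternative — NERC,
*Non-Euclidean Relational Clustering* — together with everything needed to
evaluate it: the Sørensen dissimilarity, the standard baselines, a
species-occurrence simulator with known regional structure, Rand/Adjusted
Rand scoring, and a paired simulation benchmark.

## The NERC algorithm

`nerc(d, k, restarts)` operates directly on the dissimilarity matrix. Each
restart has three steps:

1. **Initialization.** `k` sites are drawn without replacement; each seeds
   its own cluster.
2. **Allocation.** Repeatedly, the smallest dissimilarity between any
   unassigned site and any assigned site is found, and the unassigned site
   joins that cluster — single-linkage-style accretion — until every site is
   assigned. If a cluster ends this step with only one member, the restart
   re-seeds (we cap consecutive re-seeds at 100 and then raise an error,
   since unbounded retrying can spin forever on structureless input).
3. **Reallocation.** For every site, its average dissimilarity to each
   cluster is computed, excluding the site itself from its own cluster's
   average. While any site would be better placed elsewhere, *one* such
   site, chosen uniformly at random, is moved to its best cluster, and all
   averages are recomputed before the next move. The loop stops at a fixed
   point, or after `max_reassignments` (default 1000) successful moves —
   moving one site can make another suboptimal, and on noisy matrices the
   process can cycle, so the cap is load-bearing, not cosmetic.

The best restart is the one minimizing the **pooled mean within-group
distance**: the mean of `d` over all unordered within-cluster pairs, pooled
across clusters. Averaging per-cluster means instead would over-reward tiny
tight clusters; pooling weighs every pair equally.

Numerical details that matter:

* **Move rule.** A site moves only on a *strict* improvement (tolerance
  1e−12). Allowing ties would let sites oscillate between equally good
  clusters and defeat the fixed-point test.
* **Singleton guard.** A move that would leave a cluster with fewer than two
  members is skipped. The allocation step already restarts on singleton
  clusters, so the optimizer preserves the same contract; it also keeps the
  selection criterion well defined (a singleton has no within pairs).
  `converged` is `TRUE` only when *no* site — guarded or not — still prefers
  a foreign cluster, so a converged result always passes an independent
  fixed-point check.
* **Tie-breaks.** Allocation ties are broken by the lowest
  (unassigned, assigned) index pair; ties between restarts keep the first
  encountered; a site with several equally best foreign clusters takes the
  lowest-indexed one. Together with R's RNG these make `nerc()` fully
  deterministic given `seed`.
* **Cap accounting.** `max_reassignments` counts successful moves, not
  evaluations.
* **Bounds.** `2 ≤ k ≤ n/2`: fewer than 2 clusters is no partition, and more
  than `n/2` would force single-member clusters.

The method finds a local, not necessarily global, optimum; `restarts`
(default 1000) is the defence. The allocation and reallocation loops are
implemented in C++ (via Rcpp) because the benchmark runs tens of thousands
of restarts; the R-level functions `nerc_initialize()`, `nerc_allocate()`
and `nerc_reallocate()` expose the individual steps for inspection and
testing.

## Dissimilarities

`sorensen_dist()` computes `1 − 2a/(2a + b + c)` between site columns after
reducing counts to presence/absence (`a` shared species, `b`/`c` unique to
each site). Sites with no species are rejected — their dissimilarity to
anything is undefined — and the simulator, not the distance code, is
responsible for never producing them. File input accepts a square
labelled CSV or a headerless strict lower triangle (mirrored on read);
asymmetries beyond 1e−9 are an error rather than silently averaged.

## Baselines

* `linkage_partition()` — single, complete, or UPGMA (average) linkage via
  `stats::hclust`, cut to exactly `k` groups with `stats::cutree`.
* `pcoa()` — classical principal coordinates: double-centre `−d²/2`,
  eigendecompose, keep positive-eigenvalue axes scaled by `√λ`. This equals
  unconstrained distance-based RDA, which is how the ordination is usually
  reached in this literature. Sørensen matrices are non-Euclidean, so
  negative eigenvalues appear; we drop those axes and apply no
  Cailliez/Lingoes correction, matching the default behaviour of the
  standard ordination tools and keeping the Euclidean-vs-non-Euclidean
  comparison about the input metric rather than the correction.
* `kmeans_partition()` — `stats::kmeans` on all retained axes (no further
  truncation), best of `restarts` (default 100) random starts. Two
  degenerate inputs need care: `k` equal to the number of points (each point
  its own cluster) and fewer distinct points than `k` (duplicates grouped,
  then split; zero scatter preserved), both of which `stats::kmeans` refuses.
* `kmeans_occurrence()` — the two pipeline variants: Sørensen → PCoA →
  k-means, and Euclidean distances on the presence/absence vectors → PCoA →
  k-means.

## Rand and Adjusted Rand

`rand_index()` is the proportion of concordant site pairs;
`adjusted_rand_index()` is the Hubert–Arabie chance-corrected form computed
from the pair contingency table. When the adjustment's denominator vanishes
(both partitions all singletons or both one cluster), we define the value as
1 if the partitions are identical up to relabelling and 0 otherwise — the
dominant convention, and the one that keeps "ARI = 1 iff same partition"
true in the edge cases the degenerate simulations can produce.

## The simulator

`sim_occurrence()` generates a species × site count matrix with known
regional structure:

* `round(e · n_species)` species are **endemic**, split as evenly as
  possible across regions (earlier regions take any remainder, so pools are
  deterministic); the rest are **cosmopolitan**, present in every region's
  pool. `e` is the endemicity: it controls how distinct the regions are.
* Each locality draws a *fresh* log-normal relative abundance for every
  species in its region's pool, then draws a fixed number of specimens by
  weighted sampling with replacement. Absence of a pool species from a
  locality is therefore an emergent property of finite sampling from a
  skewed abundance distribution, not a separate zero-inflation step, and
  abundance ranks are uncorrelated between localities.

Defaults, chosen once as a realistic fossil-assemblage regime and not
revisited: 200 species, 3 regions × 30 sites (the benchmark design),
endemicity 0.4, 50 specimens per site, log-normal `meanlog = 0`,
`sdlog = 1.5`. The `sdlog` value gives a handful of dominant species and a
long tail of rare ones — the shape empirical abundance distributions show —
and at 10× pool-size sampling still leaves the rarest species unobserved in
a noticeable fraction of draws, which is the realistic part of the regime.

The per-site specimen count is *fixed*, not Poisson-varying: sampling
intensity sweeps vary the fixed count, and a variable-effort toggle is a
natural extension point. Two consequences are worth knowing. First, column
sums are exactly the specimen count, which makes tests sharp. Second, site
richness is nearly homogeneous, so Euclidean distance on presence/absence
vectors (≈ √(b+c)) orders site pairs almost identically to Sørensen
((b+c)/(2a+b+c)); differences between the two k-means variants are
correspondingly small under this generator, whereas real surveys with
heterogeneous effort can separate them sharply. The generator also has no
spatial geography, dispersal, or taphonomic bias — passing benchmarks here
shows the methods recover *compositional* regional signal from noisy finite
sampling, nothing more.

## The benchmark

`run_replicate()` simulates one matrix and feeds the *same* matrix to all
six method/input combinations (three linkage methods, two k-means variants,
NERC), scoring each against the true regional labels with the ARI; a method
failure records `NA` rather than aborting the replicate. `run_sweep()`
repeats this `n_reps` times per level of either endemicity or sampling
intensity, with per-replicate seeds derived deterministically from
`(seed, level, replicate)`, so the design is paired: within a replicate,
method differences are never simulation noise. `autoplot()` draws the
mean-ARI curves with ±2 SE ribbons.

Design choices for the sweeps:

* `n_reps` defaults to 100 (1000 is available by argument); standard errors
  at 100 replicates are already small relative to the method gaps of
  interest.
* NERC runs 100 restarts per replicate inside the benchmark (not the
  standalone default of 1000); in paired comparisons the extra restarts
  change third-decimal ARI at most, and the benchmark runs six hundred
  thousand restarts as it is.
* Default grids: endemicity `{0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9}` and
  specimens per site `{30, 50, 75, 100, 200}`. The grids are the package's
  own: under the default generator, below ~25 specimens per site (or below
  endemicity ~0.2 at 50 specimens) *every* method is at chance and the sweep
  carries no information, so the sparse end starts at 30, the sparsest level
  with recoverable signal.

The interesting regimes, which the test suite checks at the full
90-site design with 100 replicates, are the two calibration extremes (no
signal at `e = 0`; universal recovery at `e = 0.9` with 200 specimens) and
the weak-signal middle (`e ∈ {0.3, 0.5}` at 50 specimens; 30 specimens at
`e = 0.4`), where the non-hierarchical methods hold their advantage over
tree cutting and single linkage sits at the bottom — single linkage's
failure mode being the far-outlier site that becomes its own cluster when
the tree is cut, a pathology NERC's singleton guard excludes by
construction.

## Known limitations

* `k` must be supplied; the method assumes true divisions exist and offers
  no internal model selection.
* NERC's reallocation can cycle on structureless matrices; such restarts
  end at the move cap with `converged = FALSE`, and the restart-best result
  may then not be a fixed point.
* The simulator's fixed per-site effort and lack of spatial structure are
  idealizations (see above); conclusions about the Euclidean-metric k-means
  variant in particular are sensitive to effort heterogeneity that this
  generator deliberately does not model.
* Hard problems (many sites, weak structure) make the allocation step's
  singleton restarts more frequent at large `k`; the 100-retry cap turns
  pathological inputs into an explicit error rather than a hang.
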
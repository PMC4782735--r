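# nerclust

Non-hierarchical, non-Euclidean clustering of species occurrence data, with
the simulation benchmark to judge it against the standard alternatives.

## What problem this solves

Biogeographic and palaeoecological studies cluster localities into faunal
regions from species × site occurrence matrices. The usual route —
ecological dissimilarity + hierarchical clustering + tree cutting — has two
structural problems: ecological indices such as Sørensen are non-Euclidean,
and a dendrogram imposes a nested, tree-like history on data whose regional
structure is reticulate. Tree cutting is also brittle: one far-outlier site
can claim an entire cluster for itself.

`nerclust` implements **NERC** (Non-Euclidean Relational Clustering), an
iterative partitioning method that works directly on the dissimilarity
matrix. Given a site dissimilarity matrix `d` and a cluster count `k`, each
restart:

1. seeds `k` clusters with randomly drawn sites,
2. grows them by repeatedly attaching the unassigned site with the smallest
   dissimilarity to any assigned site (single-linkage-style accretion),
   re-seeding if a cluster ends up with one member,
3. then optimizes: while any site has a strictly smaller average
   dissimilarity to a foreign cluster than to its own (self excluded), one
   such site chosen at random is moved and all averages recomputed, up to a
   cap of 1000 moves.

Over many restarts (default 1000) the partition minimizing the pooled mean
within-cluster dissimilarity

```
W(P) = mean{ d(i, j) : i < j, cluster(i) = cluster(j) }
```

is returned. The result is a local optimum in the sense that no single site
prefers another cluster — a fixed point the package can verify
independently.

Alongside the estimator the package provides the full evaluation apparatus:
Sørensen (Dice) dissimilarities, single/complete/UPGMA linkage with tree
cutting, principal-coordinates ordination + k-means (Sørensen and Euclidean
variants), Rand and Adjusted Rand indices, a species-occurrence simulator
with known regional structure (tunable endemicity and sampling intensity),
and a paired benchmark sweeping either parameter across all six methods.

## Worked example

```r
library(nerclust)

# 3 regions x 30 sites, half the 200-species pool endemic, 50 specimens/site
occ <- sim_occurrence(n_species = 200, n_regions = 3, sites_per_region = 30,
                      endemicity = 0.5, specimens_per_site = 50, seed = 42)
d <- sorensen_dist(occ)

fit <- nerc(d, k = 3, restarts = 200, seed = 1)
fit
#> Non-Euclidean Relational Clustering
#>   90 sites in 3 clusters (sizes: 29, 30, 31)
#>   mean within-group distance: 0.792468
#>   restarts: 200; reassignments in best restart: 59; converged: TRUE

adjusted_rand_index(fit$cluster, true_regions(occ))
#> [1] 0.9664753

adjusted_rand_index(linkage_partition(d, "upgma", 3), true_regions(occ))
#> [1] 0.0006594543
```

At this moderate endemicity NERC recovers the three regions almost exactly
(ARI 0.97; 1 would be a perfect match), while UPGMA plus tree cutting is at
chance (ARI ≈ 0) — the regime where the choice of clustering method
actually matters. `tidy(fit)` gives the site-to-cluster table, `glance(fit)`
the fit summary. The benchmark is one call:

```r
bm <- run_sweep("endemicity", levels = c(0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9),
                n_reps = 100, seed = 1)
autoplot(bm)   # mean ARI per method vs endemicity, ±2 SE ribbons
```

A thin command-line wrapper over the same functions is installed at
`inst/scripts/nerclust-cli.R` (subcommands `simulate`, `dist`, `nerc`,
`linkage`, `kmeans`, `evaluate`, `benchmark`).

See `vignettes/nerc-methods.Rmd` for the algorithmic details, simulator
design, and the reasoning behind every tunable default.

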
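#' Regional species pools
#'
#' Splits a species pool into endemic and cosmopolitan components.
#' `round(endemicity * n_species)` species are endemic to exactly one region,
#' divided as evenly as possible across regions (earlier regions receive any
#' remainder); all remaining species are cosmopolitan and belong to every
#' region's pool. The split is deterministic given the parameters.
#'
#' @param n_species Total species pool size.
#' @param n_regions Number of regions (at least 2).
#' @param endemicity Proportion of all species endemic to a single region,
#'   in `[0, 1]`.
#' @return A list with one integer vector of species indices per region.
#' @export
#' @examples
#' pools <- build_species_pools(100, 3, 0.3)
#' lengths(pools)  # 80 80 80: 10 endemics each + 70 cosmopolitan
build_species_pools <- function(n_species, n_regions, endemicity) {
  stopifnot(n_species >= 1, n_regions >= 2, endemicity >= 0, endemicity <= 1)
  n_end <- round(endemicity * n_species)
  per_region <- rep(n_end %/% n_regions, n_regions) +
    (seq_len(n_regions) <= n_end %% n_regions)
  cosmo <- if (n_end < n_species) (n_end + 1):n_species else integer(0)
  ends <- cumsum(per_region)
  starts <- ends - per_region + 1
  pools <- lapply(seq_len(n_regions), function(r) {
    endemics <- if (per_region[r] > 0) starts[r]:ends[r] else integer(0)
    c(endemics, cosmo)
  })
  if (any(lengths(pools) == 0)) {
    stop("a region has an empty species pool; increase n_species or endemicity")
  }
  pools
}

#' Sample one locality from a regional species pool
#'
#' Draws a fresh log-normal relative abundance for every species in the pool,
#' then draws a fixed number of specimens by weighted sampling with
#' replacement. Species outside the pool get a zero count; species inside the
#' pool may be absent simply because no specimen of them was drawn, which is
#' how sparse sampling arises.
#'
#' @param pool Integer vector of species indices available in the region.
#' @param n_species Total species count (length of the returned vector).
#' @param specimens_per_site Number of specimens to draw (at least 1).
#' @param meanlog,sdlog Log-normal abundance distribution parameters.
#' @return Integer count vector of length `n_species` summing to
#'   `specimens_per_site`.
#' @export
sample_locality <- function(pool, n_species, specimens_per_site,
                            meanlog = 0, sdlog = 1.5) {
  stopifnot(length(pool) >= 1, specimens_per_site >= 1)
  for (attempt in seq_len(100)) {
    abund <- stats::rlnorm(length(pool), meanlog, sdlog)
    draws <- sample.int(length(pool), specimens_per_site,
                        replace = TRUE, prob = abund)
    counts <- integer(n_species)
    counts[pool] <- tabulate(draws, nbins = length(pool))
    if (any(counts > 0)) return(counts)
  }
  stop("failed to draw a non-empty locality in 100 attempts")
}

#' Simulate a species occurrence matrix with known regional clusters
#'
#' Generates a species-by-site count matrix in which sites belong to regions
#' with partially distinct species pools: a proportion `endemicity` of the
#' species are endemic to a single region and the rest are cosmopolitan.
#' Every locality is an independent weighted-with-replacement draw of
#' `specimens_per_site` specimens from its region's pool under a freshly
#' randomized log-normal abundance distribution, so abundance ranks are not
#' shared between localities. Columns are grouped by region and the true
#' region of every site is recorded in the `true_regions` attribute.
#'
#' @inheritParams build_species_pools
#' @param sites_per_region Number of localities simulated per region.
#' @param specimens_per_site Specimens drawn per locality (sampling
#'   intensity); fixed per site, so column sums equal this value exactly.
#' @param meanlog,sdlog Log-normal abundance shape; the defaults give a few
#'   dominant species and a long tail of rare ones.
#' @param seed Optional RNG seed for reproducibility.
#' @return An integer matrix (`n_species` rows, `n_regions * sites_per_region`
#'   columns) with a `true_regions` attribute: an integer region label per
#'   site, named by site id.
#' @seealso [true_regions()], [run_replicate()]
#' @export
#' @examples
#' occ <- sim_occurrence(n_species = 60, n_regions = 3, sites_per_region = 5,
#'                       endemicity = 0.5, specimens_per_site = 40, seed = 1)
#' dim(occ)
#' table(true_regions(occ))
sim_occurrence <- function(n_species = 200, n_regions = 3,
                           sites_per_region = 30, endemicity = 0.4,
                           specimens_per_site = 50,
                           meanlog = 0, sdlog = 1.5, seed = NULL) {
  stopifnot(sites_per_region >= 1, specimens_per_site >= 1)
  if (!is.null(seed)) set.seed(seed)
  pools <- build_species_pools(n_species, n_regions, endemicity)
  n_sites <- n_regions * sites_per_region
  m <- matrix(0L, n_species, n_sites)
  regions <- rep(seq_len(n_regions), each = sites_per_region)
  for (s in seq_len(n_sites)) {
    m[, s] <- sample_locality(pools[[regions[s]]], n_species,
                              specimens_per_site, meanlog, sdlog)
  }
  rownames(m) <- sprintf("sp%03d", seq_len(n_species))
  colnames(m) <- sprintf("r%ds%02d", regions,
                         rep(seq_len(sites_per_region), n_regions))
  names(regions) <- colnames(m)
  attr(m, "true_regions") <- regions
  m
}

#' True region labels of a simulated occurrence matrix
#'
#' @param x A matrix produced by [sim_occurrence()].
#' @return Named integer vector of region labels, one per site.
#' @export
true_regions <- function(x) {
  r <- attr(x, "true_regions")
  if (is.null(r)) stop("no 'true_regions' attribute on this matrix")
  r
}
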
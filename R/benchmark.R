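BENCH_METHODS <- c("single", "complete", "upgma",
                   "kmeans_euclidean", "kmeans_sorensen", "nerc")

#' Cluster one simulated occurrence matrix with all six methods
#'
#' Simulates a single occurrence matrix, computes its Sorensen dissimilarity
#' matrix once, and applies the six method/input combinations of the
#' benchmark to that same matrix: single, complete and UPGMA linkage with
#' tree cutting; k-means on a principal-coordinates ordination of Euclidean
#' and of Sorensen distances; and NERC. Each result is scored by the Adjusted
#' Rand Index against the known regional labels. Because all methods see the
#' identical matrix, method differences within a replicate are not simulation
#' noise.
#'
#' @inheritParams sim_occurrence
#' @param k Number of clusters requested from every method; defaults to the
#'   number of simulated regions.
#' @param nerc_restarts NERC restarts per replicate (default 100).
#' @param kmeans_restarts k-means restarts per replicate (default 100).
#' @return A tibble with columns `method` and `ari`; a method failure yields
#'   `NA` rather than an error.
#' @export
run_replicate <- function(n_species = 200, n_regions = 3,
                          sites_per_region = 30, endemicity = 0.4,
                          specimens_per_site = 50, k = n_regions,
                          nerc_restarts = 100, kmeans_restarts = 100,
                          meanlog = 0, sdlog = 1.5, seed = NULL) {
  occ <- sim_occurrence(n_species, n_regions, sites_per_region, endemicity,
                        specimens_per_site, meanlog, sdlog, seed = seed)
  truth <- true_regions(occ)
  pa <- as_presence_absence(occ)
  ds <- sorensen_dist(pa)

  fits <- list(
    single   = function() linkage_partition(ds, "single", k),
    complete = function() linkage_partition(ds, "complete", k),
    upgma    = function() linkage_partition(ds, "upgma", k),
    kmeans_euclidean = function()
      kmeans_partition(pcoa(stats::dist(t(pa))), k, kmeans_restarts),
    kmeans_sorensen = function()
      kmeans_partition(pcoa(ds), k, kmeans_restarts),
    nerc = function()
      nerc(ds, k, restarts = nerc_restarts)$cluster
  )
  ari <- vapply(fits, function(f) {
    tryCatch(adjusted_rand_index(f(), truth), error = function(e) NA_real_)
  }, numeric(1))
  tibble::tibble(method = BENCH_METHODS, ari = unname(ari[BENCH_METHODS]))
}

#' Benchmark sweep over endemicity or sampling intensity
#'
#' Repeats [run_replicate()] `n_reps` times at every level of the swept
#' parameter and summarizes the Adjusted Rand Index per method. The design is
#' paired: within a replicate all six methods cluster the identical simulated
#' matrix. Per-replicate seeds are derived deterministically from
#' `(seed, level, replicate)`, so a sweep is reproducible and each replicate
#' independent.
#'
#' @param experiment `"endemicity"` (levels are endemicity proportions) or
#'   `"sampling"` (levels are specimens per site).
#' @param levels Numeric vector of at least two swept parameter values.
#' @param n_reps Replicates per level (default 100).
#' @param seed Master seed for the sweep.
#' @inheritParams run_replicate
#' @return A tibble of class `"nerc_benchmark"` with columns `experiment`,
#'   `level`, `method`, `mean_ari`, `se_ari`, `n_reps`. Has an [autoplot()]
#'   method mirroring the mean-ARI-versus-parameter comparison figures.
#' @export
#' @examples
#' \donttest{
#' bm <- run_sweep("endemicity", levels = c(0.2, 0.6), n_reps = 5,
#'                 sites_per_region = 5, n_species = 60, seed = 1)
#' bm
#' }
run_sweep <- function(experiment = c("endemicity", "sampling"), levels,
                      n_reps = 100, seed = 1, n_species = 200, n_regions = 3,
                      sites_per_region = 30, endemicity = 0.4,
                      specimens_per_site = 50, nerc_restarts = 100,
                      kmeans_restarts = 100, meanlog = 0, sdlog = 1.5) {
  experiment <- match.arg(experiment)
  stopifnot(length(levels) >= 2, n_reps >= 1)
  rows <- list()
  for (li in seq_along(levels)) {
    lev <- levels[li]
    reps <- lapply(seq_len(n_reps), function(r) {
      args <- list(n_species = n_species, n_regions = n_regions,
                   sites_per_region = sites_per_region,
                   endemicity = endemicity,
                   specimens_per_site = specimens_per_site,
                   k = n_regions, nerc_restarts = nerc_restarts,
                   kmeans_restarts = kmeans_restarts,
                   meanlog = meanlog, sdlog = sdlog,
                   seed = replicate_seed(seed, li, r))
      if (experiment == "endemicity") args$endemicity <- lev
      else args$specimens_per_site <- lev
      dplyr::mutate(do.call(run_replicate, args), rep = r)
    })
    rows[[li]] <- dplyr::mutate(dplyr::bind_rows(reps), level = lev)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::summarise(
    dplyr::group_by(out, .data$level, .data$method),
    mean_ari = mean(.data$ari, na.rm = TRUE),
    se_ari = stats::sd(.data$ari, na.rm = TRUE) /
      sqrt(sum(!is.na(.data$ari))),
    n_reps = sum(!is.na(.data$ari)),
    .groups = "drop")
  out <- dplyr::arrange(
    tibble::as_tibble(dplyr::mutate(out, experiment = experiment,
                                    .before = 1)),
    .data$level, .data$method)
  class(out) <- c("nerc_benchmark", class(out))
  out
}

replicate_seed <- function(master, level_index, rep) {
  as.integer((master * 1000003 + level_index * 75029 + rep * 7919) %%
               2147483629)
}

#' Plot a benchmark table
#'
#' Mean Adjusted Rand Index per method against the swept parameter, with
#' ±2 standard error ribbons — the standard way these method comparisons are
#' displayed.
#'
#' @param object A `"nerc_benchmark"` tibble from [run_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nerc_benchmark
#' @export
autoplot.nerc_benchmark <- function(object, ...) {
  xlab <- if (object$experiment[1] == "endemicity") {
    "Endemicity (proportion of endemic species)"
  } else {
    "Sampling intensity (specimens per site)"
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$level, .data$mean_ari,
                                       colour = .data$method,
                                       fill = .data$method)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_ari - 2 * .data$se_ari,
                                      ymax = .data$mean_ari + 2 * .data$se_ari),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "Mean Adjusted Rand Index",
                  colour = "Method", fill = "Method") +
    ggplot2::theme_minimal()
}

#' @method glance nerc_benchmark
#' @export
glance.nerc_benchmark <- function(x, ...) {
  tibble::tibble(experiment = x$experiment[1],
                 n_levels = length(unique(x$level)),
                 n_methods = length(unique(x$method)),
                 n_reps = max(x$n_reps))
}
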
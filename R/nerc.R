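#' Non-Euclidean Relational Clustering (NERC)
#'
#' Partitions the sites of a dissimilarity matrix into `k` clusters by an
#' iterative, non-hierarchical procedure. Each restart has three steps:
#' (1) *initialization* — `k` sites are sampled without replacement and each
#' seeds its own cluster; (2) *allocation* — repeatedly, the globally smallest
#' dissimilarity between any unassigned and any assigned site joins the
#' unassigned site to that cluster (as in single linkage), until all sites are
#' assigned; if any cluster then has a single member the restart re-seeds;
#' (3) *reallocation* — while any site is on average closer to a foreign
#' cluster than to its own (self excluded), one such site chosen at random is
#' moved and all averages are recomputed, up to `max_reassignments` moves.
#' The best of `restarts` independent restarts by pooled mean within-group
#' distance is returned.
#'
#' Moves that would leave a cluster with fewer than two members are skipped,
#' preserving the k-cluster contract; `converged` is `TRUE` only if no site at
#' all still prefers a foreign cluster. The method finds a local, not
#' necessarily global, optimum, hence the many restarts.
#'
#' @param d A `dist` object or square symmetric dissimilarity matrix with
#'   zero diagonal.
#' @param k Number of clusters: an integer between 2 and half the number of
#'   sites. Fewer than 2 would place everything in one group; more than `n/2`
#'   would force single-member clusters.
#' @param restarts Number of independent restarts (default 1000).
#' @param max_reassignments Cap on successful moves per restart, guarding
#'   against cycling when no fully optimal arrangement exists.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called so
#'   the result is reproducible.
#' @param verbose Print the restart counter while running.
#' @return An object of class `"nerc"`: a list with `cluster` (named integer
#'   vector of cluster ids in `1..k`), `k`, `mean_within_distance` (the pooled
#'   mean dissimilarity over all within-cluster pairs, the selection
#'   criterion), `restarts_run`, `reassignments_used` (successful moves in the
#'   winning restart) and `converged`. Has [tidy()], [glance()] and `print`
#'   methods.
#' @seealso The package vignette for the algorithmic details and the
#'   reasoning behind the defaults; [run_sweep()] for the simulation
#'   benchmark comparing NERC with linkage and ordination-based clustering.
#' @export
#' @examples
#' occ <- sim_occurrence(n_species = 60, sites_per_region = 4,
#'                       endemicity = 0.8, specimens_per_site = 60, seed = 4)
#' fit <- nerc(sorensen_dist(occ), k = 3, restarts = 50, seed = 1)
#' fit
#' adjusted_rand_index(fit$cluster, true_regions(occ))
nerc <- function(d, k = 2, restarts = 1000, max_reassignments = 1000,
                 seed = NULL, verbose = FALSE) {
  m <- as_dissimilarity_matrix(d)
  n <- nrow(m)
  check_k(k, n)
  stopifnot(restarts >= 1, max_reassignments >= 0)
  if (!is.null(seed)) set.seed(seed)

  best <- NULL
  for (r in seq_len(restarts)) {
    if (verbose) message("restart ", r, "/", restarts)
    labels <- allocate_with_retries(m, k)
    out <- cpp_nerc_reallocate(m, labels, k, as.integer(max_reassignments),
                               1e-12)
    score <- cpp_mean_within(m, out$labels)
    if (is.null(best) || score < best$score) {
      best <- list(labels = out$labels, score = score,
                   reassignments = out$reassignments,
                   converged = out$converged && !out$stalled)
    }
  }

  cluster <- as.integer(best$labels)
  names(cluster) <- rownames(m)
  structure(list(cluster = cluster, k = as.integer(k),
                 mean_within_distance = best$score,
                 restarts_run = as.integer(restarts),
                 reassignments_used = best$reassignments,
                 converged = best$converged),
            class = "nerc")
}

# initialization + allocation, re-seeding when a cluster ends up a singleton
allocate_with_retries <- function(m, k, max_retries = 100) {
  for (try in seq_len(max_retries)) {
    labels <- nerc_allocate(m, nerc_initialize(m, k))
    if (!attr(labels, "singleton")) return(as.integer(labels))
  }
  stop("allocation produced a singleton cluster in ", max_retries,
       " consecutive attempts; the data may not support k = ", k, " clusters")
}

check_k <- function(k, n) {
  if (!is.numeric(k) || length(k) != 1 || k != round(k)) {
    stop("`k` must be a single integer")
  }
  if (k < 2) stop("`k` must be at least 2 (one cluster is no partition)")
  if (k > floor(n / 2)) {
    stop("`k` must be no greater than half the number of samples (",
         floor(n / 2), " for n = ", n, ") to prevent clusters of one")
  }
  invisible(TRUE)
}

#' NERC initialization: seed k singleton clusters
#'
#' Samples `k` sites without replacement; each becomes the sole member of one
#' of the `k` clusters. Uses the current RNG state.
#'
#' @inheritParams nerc
#' @return Integer vector with cluster ids `1..k` at the seed positions and
#'   `NA` elsewhere.
#' @export
nerc_initialize <- function(d, k) {
  m <- as_dissimilarity_matrix(d)
  check_k(k, nrow(m))
  labels <- rep(NA_integer_, nrow(m))
  labels[sample.int(nrow(m), k)] <- seq_len(k)
  names(labels) <- rownames(m)
  labels
}

#' NERC allocation: single-linkage-style growth of the seeded clusters
#'
#' Repeatedly finds the smallest dissimilarity between any unassigned site and
#' any assigned site and assigns the unassigned site to that cluster, until
#' every site is assigned. Ties are broken by the lowest
#' (unassigned index, assigned index) pair so the step is deterministic.
#'
#' @inheritParams nerc
#' @param partial Labels as returned by [nerc_initialize()]: exactly `k`
#'   seeds, `NA` for unassigned sites.
#' @return Complete integer label vector with a logical attribute
#'   `"singleton"`, `TRUE` when some cluster ended up with a single member
#'   (the signal to restart from initialization).
#' @export
nerc_allocate <- function(d, partial) {
  m <- as_dissimilarity_matrix(d)
  stopifnot(length(partial) == nrow(m), any(!is.na(partial)))
  labels <- cpp_nerc_allocate(m, as.integer(partial))
  names(labels) <- rownames(m)
  k <- max(labels)
  attr(labels, "singleton") <- any(tabulate(labels, k) < 2)
  labels
}

#' NERC reallocation: iterative one-at-a-time optimization
#'
#' Moves one randomly chosen suboptimal site at a time to the cluster it is on
#' average most similar to, recomputing all site-to-cluster average distances
#' after every move, until no site can improve or `max_reassignments` moves
#' have been made. A site's distance to its own cluster excludes itself; moves
#' that would leave a cluster with fewer than two members are skipped.
#'
#' @inheritParams nerc
#' @param labels Complete integer cluster labels in `1..k`, every cluster with
#'   at least two members.
#' @return A list with `labels`, `reassignments` (successful moves) and
#'   `converged` (`TRUE` iff no site prefers a foreign cluster).
#' @export
nerc_reallocate <- function(d, labels, max_reassignments = 1000) {
  m <- as_dissimilarity_matrix(d)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(m), !anyNA(labels))
  k <- max(labels)
  sizes <- tabulate(labels, k)
  if (any(sizes < 2)) stop("every cluster must have at least two members")
  out <- cpp_nerc_reallocate(m, labels, k, as.integer(max_reassignments),
                             1e-12)
  lab <- as.integer(out$labels)
  names(lab) <- rownames(m)
  list(labels = lab, reassignments = out$reassignments,
       converged = out$converged && !out$stalled)
}

#' Pooled mean within-group distance of a partition
#'
#' The mean of the dissimilarities over all unordered pairs of sites that
#' share a cluster, pooled across clusters. This is the criterion NERC
#' minimizes across restarts; pooling (rather than averaging per-cluster
#' means) avoids over-rewarding tiny tight clusters.
#'
#' @inheritParams nerc
#' @param labels Complete cluster labels; every cluster needs at least two
#'   members so that it contributes at least one pair.
#' @return A non-negative scalar.
#' @export
mean_within_group_distance <- function(d, labels) {
  m <- as_dissimilarity_matrix(d)
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(m), !anyNA(labels))
  if (any(tabulate(labels, max(labels)) < 2)) {
    stop("singleton cluster: within-group distance is undefined")
  }
  cpp_mean_within(m, labels)
}

#' @export
print.nerc <- function(x, ...) {
  cat("Non-Euclidean Relational Clustering\n")
  cat(sprintf("  %d sites in %d clusters (sizes: %s)\n", length(x$cluster),
              x$k, paste(tabulate(x$cluster, x$k), collapse = ", ")))
  cat(sprintf("  mean within-group distance: %.6g\n", x$mean_within_distance))
  cat(sprintf("  restarts: %d; reassignments in best restart: %d; converged: %s\n",
              x$restarts_run, x$reassignments_used, x$converged))
  invisible(x)
}

#' @rdname nerc
#' @param x A `"nerc"` object.
#' @param ... Unused.
#' @method tidy nerc
#' @export
tidy.nerc <- function(x, ...) {
  tibble::tibble(site = names(x$cluster), cluster = unname(x$cluster))
}

#' @rdname nerc
#' @method glance nerc
#' @export
glance.nerc <- function(x, ...) {
  tibble::tibble(k = x$k,
                 mean_within_distance = x$mean_within_distance,
                 restarts_run = x$restarts_run,
                 reassignments_used = x$reassignments_used,
                 converged = x$converged)
}
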
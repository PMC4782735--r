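#' Agglomerative clustering cut to k groups
#'
#' Builds a single, complete or UPGMA (average) linkage dendrogram from a
#' dissimilarity matrix with [stats::hclust()] and cuts it into exactly `k`
#' discrete clusters with [stats::cutree()].
#'
#' @inheritParams nerc
#' @param method One of `"single"`, `"complete"`, `"upgma"`.
#' @param k Number of clusters, `2 <= k <= n`.
#' @return Named integer vector of cluster labels in `1..k`.
#' @export
linkage_partition <- function(d, method = c("single", "complete", "upgma"),
                              k = 2) {
  method <- match.arg(method)
  m <- as_dissimilarity_matrix(d)
  n <- nrow(m)
  if (k < 2 || k > n) stop("`k` must be between 2 and the number of sites")
  hc <- stats::hclust(stats::as.dist(m),
                      method = switch(method, upgma = "average", method))
  stats::cutree(hc, k = k)
}

#' Principal coordinates analysis (classical MDS)
#'
#' Embeds a dissimilarity matrix into Euclidean coordinates: the matrix of
#' `-d^2/2` is double-centred and eigendecomposed; axes with positive
#' eigenvalues are retained and scaled by the square root of their eigenvalue.
#' This is the unconstrained case of distance-based redundancy analysis.
#' Non-Euclidean dissimilarities such as Sorensen typically produce some
#' negative eigenvalues; those axes are dropped without correction, which
#' matches the default behaviour of the standard ordination tools.
#'
#' @inheritParams nerc
#' @return An object of class `"pcoa_ordination"`: list with `coordinates`
#'   (sites x retained axes, columns centred) and `eigenvalues` (all `n`
#'   eigenvalues, decreasing; negatives reported but not retained).
#' @export
pcoa <- function(d) {
  m <- as_dissimilarity_matrix(d)
  n <- nrow(m)
  a <- -0.5 * m^2
  rm_ <- rowMeans(a); cm_ <- colMeans(a); gm <- mean(a)
  g <- a - outer(rm_, rep(1, n)) - outer(rep(1, n), cm_) + gm
  e <- eigen(g, symmetric = TRUE)
  eps <- max(abs(e$values)) * sqrt(.Machine$double.eps)
  keep <- which(e$values > eps)
  if (length(keep) == 0) stop("no positive eigenvalues: degenerate input")
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), length(keep))
  rownames(coords) <- rownames(m)
  colnames(coords) <- paste0("PCo", seq_along(keep))
  structure(list(coordinates = coords, eigenvalues = e$values),
            class = "pcoa_ordination")
}

#' k-means on ordination coordinates
#'
#' Runs [stats::kmeans()] on the retained principal-coordinate axes (or any
#' point matrix), keeping the best of `restarts` random initializations by
#' within-cluster sum of squares. Deterministic given the RNG state. When the
#' points contain fewer than `k` distinct rows (degenerate input on which the
#' standard initializer cannot place distinct centers), duplicates are grouped
#' and groups split until `k` non-empty clusters exist, preserving zero
#' within-cluster scatter.
#'
#' @param coords A `"pcoa_ordination"` object or a numeric matrix of points.
#' @param k Number of clusters, at most the number of points.
#' @param restarts Random initializations (default 100).
#' @return Named integer vector of cluster labels in `1..k`.
#' @export
kmeans_partition <- function(coords, k, restarts = 100) {
  x <- if (inherits(coords, "pcoa_ordination")) coords$coordinates else coords
  x <- as.matrix(x)
  n <- nrow(x)
  if (k > n) stop("`k` cannot exceed the number of points")
  n_distinct <- nrow(unique(x))
  if (n_distinct < k) {
    lab <- match(apply(x, 1, paste, collapse = "\r"),
                 unique(apply(x, 1, paste, collapse = "\r")))
    # split largest groups until k non-empty clusters
    nxt <- max(lab) + 1
    while (max(lab) < k) {
      big <- which(tabulate(lab) > 1)[1]
      i <- which(lab == big)[1]
      lab[i] <- nxt
      nxt <- nxt + 1
    }
    names(lab) <- rownames(x)
    return(lab)
  }
  if (k == n) {  # stats::kmeans rejects k == n; trivially each point alone
    lab <- seq_len(n)
    names(lab) <- rownames(x)
    return(lab)
  }
  km <- stats::kmeans(x, centers = k, nstart = restarts, iter.max = 100)
  lab <- km$cluster
  names(lab) <- rownames(x)
  lab
}

#' k-means clustering of an occurrence matrix via ordination
#'
#' The two ordination-based pipelines of the benchmark: the occurrence matrix
#' is reduced to presence/absence, pairwise site distances are computed with
#' either the Sorensen (non-Euclidean) index or the Euclidean metric, the
#' distances are embedded by [pcoa()], and [kmeans_partition()] clusters the
#' retained axes.
#'
#' @param x Species-by-site occurrence matrix.
#' @param k Number of clusters.
#' @param metric `"sorensen"` or `"euclidean"`.
#' @param restarts k-means restarts.
#' @return Named integer vector of cluster labels.
#' @export
kmeans_occurrence <- function(x, k, metric = c("sorensen", "euclidean"),
                              restarts = 100) {
  metric <- match.arg(metric)
  pa <- as_presence_absence(x)
  d <- switch(metric,
              sorensen = sorensen_dist(pa),
              euclidean = stats::dist(t(pa)))
  kmeans_partition(pcoa(d), k, restarts = restarts)
}
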
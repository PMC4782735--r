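#' Contingency table between two partitions
#'
#' @param a,b Cluster label vectors of equal length (any label type).
#' @return Integer matrix `n_ij` of sites shared between cluster `i` of `a`
#'   and cluster `j` of `b`.
#' @keywords internal
pair_contingency <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  unname(table(a, b))
}

#' Rand Index between two partitions
#'
#' The proportion of site pairs on which two partitions agree: pairs placed
#' together in both partitions or apart in both, out of all `choose(n, 2)`
#' pairs. 1 is a perfect match; invariant to cluster relabelling.
#'
#' @param a,b Cluster label vectors of equal length (`n >= 2`).
#' @return A value in `[0, 1]`.
#' @export
#' @examples
#' rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # 1/3
rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) stop("need at least two sites to compare partitions")
  ct <- pair_contingency(a, b)
  tog_both <- sum(choose(ct, 2))
  tog_a <- sum(choose(rowSums(ct), 2))
  tog_b <- sum(choose(colSums(ct), 2))
  total <- choose(n, 2)
  (total + 2 * tog_both - tog_a - tog_b) / total
}

#' Adjusted Rand Index between two partitions
#'
#' The Hubert & Arabie (1985) chance-corrected Rand Index: the pair-counting
#' agreement is rescaled so its expectation under random partitions (with the
#' observed cluster sizes) is 0 while perfect agreement stays 1. Values can be
#' slightly negative for worse-than-chance agreement.
#'
#' In the degenerate case where the maximum equals the expectation (both
#' partitions all singletons, or both a single cluster), the index is defined
#' as 1 when the partitions are identical up to relabelling and 0 otherwise.
#'
#' @param a,b Cluster label vectors of equal length (`n >= 2`).
#' @return A value `<= 1`; 1 iff the partitions are identical up to
#'   relabelling.
#' @export
#' @examples
#' adjusted_rand_index(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 3, 3))
adjusted_rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) stop("need at least two sites to compare partitions")
  ct <- pair_contingency(a, b)
  idx <- sum(choose(ct, 2))
  sa <- sum(choose(rowSums(ct), 2))
  sb <- sum(choose(colSums(ct), 2))
  expected <- sa * sb / choose(n, 2)
  maximum <- (sa + sb) / 2
  if (abs(maximum - expected) < .Machine$double.eps * max(1, maximum)) {
    identical_up_to_relabel <-
      nrow(ct) == ncol(ct) && sum(ct > 0) == nrow(ct) &&
      all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
    return(as.numeric(identical_up_to_relabel))
  }
  (idx - expected) / (maximum - expected)
}
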
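# Independent oracles and fixture builders used across the suite.

# Pair-counting oracle for the Rand and Adjusted Rand indices: explicit loops
# over all unordered site pairs, no contingency table.
oracle_pair_counts <- function(a, b) {
  n <- length(a)
  together_both <- together_a <- together_b <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) together_both <- together_both + 1L
      if (sa) together_a <- together_a + 1L
      if (sb) together_b <- together_b + 1L
    }
  }
  list(idx = together_both, sa = together_a, sb = together_b,
       total = choose(n, 2))
}

oracle_rand <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  # concordant = together in both + apart in both
  (pc$total + 2 * pc$idx - pc$sa - pc$sb) / pc$total
}

oracle_ari <- function(a, b) {
  pc <- oracle_pair_counts(a, b)
  expected <- pc$sa * pc$sb / pc$total
  maximum <- (pc$sa + pc$sb) / 2
  if (abs(maximum - expected) < 1e-12) {
    return(as.numeric(oracle_rand(a, b) == 1))
  }
  (pc$idx - expected) / (maximum - expected)
}

# All set partitions of n elements into at most kmax blocks, as restricted
# growth strings (each returned as an integer label vector).
enumerate_partitions <- function(n, kmax) {
  out <- list()
  recurse <- function(labels, used) {
    pos <- length(labels) + 1
    if (pos > n) {
      out[[length(out) + 1]] <<- labels
      return(invisible())
    }
    for (lab in seq_len(min(used + 1, kmax))) {
      recurse(c(labels, lab), max(used, lab))
    }
  }
  recurse(integer(0), 0L)
  out
}

# Independent fixed-point checker: no site may have a strictly smaller
# average distance to a foreign cluster than to its own (self excluded).
is_fixed_point <- function(m, labels, tol = 1e-12) {
  n <- nrow(m)
  k <- max(labels)
  for (i in seq_len(n)) {
    own <- labels[i]
    own_avg <- mean(m[i, labels == own & seq_len(n) != i])
    for (c in seq_len(k)) {
      if (c == own) next
      if (own_avg - mean(m[i, labels == c]) > tol) return(FALSE)
    }
  }
  TRUE
}

# Pooled mean within-group distance computed independently of the package.
oracle_mean_within <- function(m, labels) {
  vals <- c()
  n <- nrow(m)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (labels[i] == labels[j]) vals <- c(vals, m[i, j])
    }
  }
  mean(vals)
}

# Two-block dissimilarity matrix with optional noise; block 1 = sites
# 1..n1, block 2 = the rest.
two_block_matrix <- function(n1, n2, within = 0.1, between = 0.9,
                             noise = 0) {
  n <- n1 + n2
  truth <- rep(1:2, c(n1, n2))
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      base <- if (truth[i] == truth[j]) within else between
      v <- base + if (noise > 0) stats::runif(1, -noise, noise) else 0
      m[i, j] <- m[j, i] <- max(v, 1e-6)
    }
  }
  rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
  attr(m, "truth") <- truth
  m
}

# Random symmetric dissimilarity matrix in (0, 1).
random_dissimilarity <- function(n) {
  m <- matrix(0, n, n)
  v <- stats::runif(n * (n - 1) / 2, 0.05, 1)
  m[lower.tri(m)] <- v
  m <- m + t(m)
  rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
  m
}

# Best pooled mean-within score over every partition of n sites into exactly
# k clusters with >= 2 members each, by exhaustive enumeration (vectorized
# over pairs, but independent of the package's implementation).
enumerated_best_score <- function(m, k) {
  n <- nrow(m)
  ut <- upper.tri(m)
  dv <- m[ut]
  parts <- enumerate_partitions(n, k)
  best <- Inf
  for (p in parts) {
    if (max(p) != k) next
    if (any(tabulate(p, k) < 2)) next
    comem <- outer(p, p, "==")[ut]
    s <- sum(dv[comem]) / sum(comem)
    if (s < best) best <- s
  }
  best
}

# Vectorized pair-counting (co-membership over all unordered pairs); same
# quantities as oracle_pair_counts, usable at scale.
comembership <- function(p) {
  outer(p, p, "==")[upper.tri(diag(length(p)))]
}
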
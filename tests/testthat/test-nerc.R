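test_that("initialization seeds k distinct singleton clusters, reproducibly", {
  m <- random_dissimilarity(8)
  set.seed(1)
  p <- nerc_initialize(m, 3)
  expect_equal(sum(!is.na(p)), 3L)
  expect_setequal(p[!is.na(p)], 1:3)

  set.seed(1)
  expect_equal(nerc_initialize(m, 3), p)

  set.seed(2)
  p6 <- nerc_initialize(random_dissimilarity(6), 3)
  expect_equal(sum(is.na(p6)), 3L)
})

test_that("k bounds are enforced with the documented limits", {
  m <- random_dissimilarity(10)
  expect_error(nerc(m, k = 1), "at least 2")
  expect_error(nerc(m, k = 6), "half the number of samples")
  expect_error(nerc_initialize(m, 1), "at least 2")
})

test_that("allocation follows the smallest unassigned-assigned distance", {
  # two-block matrix, seeds in different blocks -> blocks recovered exactly
  m <- two_block_matrix(4, 4)
  partial <- rep(NA_integer_, 8)
  partial[1] <- 1L
  partial[5] <- 2L
  lab <- nerc_allocate(m, partial)
  expect_equal(unname(lab[1:4]), rep(1L, 4))
  expect_equal(unname(lab[5:8]), rep(2L, 4))
  expect_false(attr(lab, "singleton"))

  # chain of sites along a line with a wider gap in the middle, seeds at the
  # two ends -> each half accretes to its own end: {1,2,3} {4,5,6}
  pos <- c(0, 0.1, 0.2, 0.35, 0.45, 0.55)
  chain <- as_dissimilarity_matrix(abs(outer(pos, pos, "-")))
  partial <- rep(NA_integer_, 6)
  partial[1] <- 1L
  partial[6] <- 2L
  lab <- nerc_allocate(chain, partial)
  expect_equal(as.vector(lab), c(1L, 1L, 1L, 2L, 2L, 2L))

  # exact ties are broken by the lowest (unassigned, assigned) index pair:
  # on a perfectly even chain the first seed wins every tie and the second
  # seed is left as a singleton
  even <- as_dissimilarity_matrix(abs(outer(0:5, 0:5, "-")) / 10)
  lab2 <- nerc_allocate(even, partial)
  expect_equal(as.vector(lab2), c(1L, 1L, 1L, 1L, 1L, 2L))
  expect_true(attr(lab2, "singleton"))

  # both seeds in the same true block: allocation still assigns everything
  # and flags the singleton for the restart path
  m4 <- two_block_matrix(3, 1)  # sites 1-3 close, site 4 far
  partial <- c(1L, 2L, NA, NA)
  lab <- nerc_allocate(m4, partial)
  expect_equal(sum(is.na(lab)), 0L)
  expect_true(attr(lab, "singleton"))
})

test_that("reallocation reaches and respects the fixed point", {
  m <- two_block_matrix(4, 4)
  block <- rep(1:2, each = 4)

  # already at the fixed point: unchanged, zero moves
  set.seed(3)
  out <- nerc_reallocate(m, block)
  expect_equal(unname(out$labels), block)
  expect_equal(out$reassignments, 0L)
  expect_true(out$converged)

  # one misassigned site moves home
  mis <- c(2L, 1L, 1L, 1L, 2L, 2L, 2L, 1L)
  set.seed(4)
  out <- nerc_reallocate(m, mis)
  expect_equal(unname(out$labels), block)
  expect_true(out$converged)
  expect_true(is_fixed_point(m, out$labels))

  # equal distances everywhere: any partition is optimal
  flat <- as_dissimilarity_matrix(matrix(0.5, 6, 6) - diag(0.5, 6))
  set.seed(5)
  out <- nerc_reallocate(flat, c(1L, 1L, 2L, 2L, 1L, 2L))
  expect_equal(out$reassignments, 0L)
  expect_true(out$converged)

  expect_error(nerc_reallocate(m, c(1L, rep(2L, 7))), "two members")
})

test_that("nerc recovers planted blocks and minimizes the enumerated score", {
  m <- two_block_matrix(4, 4)
  fit <- nerc(m, k = 2, restarts = 50, seed = 9)
  expect_equal(adjusted_rand_index(fit$cluster, attr(m, "truth")), 1)
  expect_equal(fit$mean_within_distance, enumerated_best_score(m, 2),
               tolerance = 1e-12)
  expect_true(fit$converged)
  expect_equal(fit$mean_within_distance,
               mean_within_group_distance(m, fit$cluster))
})

test_that("nerc is deterministic given a seed and label-permutation invariant", {
  set.seed(21)
  m <- random_dissimilarity(14)
  f1 <- nerc(m, k = 3, restarts = 30, seed = 77)
  f2 <- nerc(m, k = 3, restarts = 30, seed = 77)
  expect_identical(f1$cluster, f2$cluster)
  expect_identical(f1$mean_within_distance, f2$mean_within_distance)

  # relabelling clusters leaves the score unchanged
  relabel <- c(2L, 3L, 1L)[f1$cluster]
  expect_equal(mean_within_group_distance(m, relabel),
               f1$mean_within_distance)
})

test_that("converged results pass the independent fixed-point checker", {
  set.seed(31)
  for (rep in 1:15) {
    m <- random_dissimilarity(16)
    fit <- nerc(m, k = sample(2:3, 1), restarts = 20)
    if (fit$converged) {
      expect_true(is_fixed_point(m, fit$cluster))
    }
    expect_equal(fit$mean_within_distance,
                 oracle_mean_within(m, fit$cluster), tolerance = 1e-12)
  }
})

test_that("mean within-group distance is the pooled pair mean", {
  # clusters {a,b} and {c,d} with d(a,b) = 0.2, d(c,d) = 0.4 -> 0.3
  m <- matrix(0.9, 4, 4)
  diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0.2
  m[3, 4] <- m[4, 3] <- 0.4
  expect_equal(mean_within_group_distance(m, c(1, 1, 2, 2)), 0.3)

  # constant matrix -> the constant, for any valid partition
  flat <- as_dissimilarity_matrix(matrix(0.7, 6, 6) - diag(0.7, 6))
  expect_equal(mean_within_group_distance(flat, c(1, 1, 1, 2, 2, 2)), 0.7)

  zero <- matrix(0, 4, 4)
  expect_equal(mean_within_group_distance(zero, c(1, 1, 2, 2)), 0)

  expect_error(mean_within_group_distance(m, c(1, 2, 2, 2)), "singleton")
})

test_that("tidy and glance summarize a nerc fit", {
  m <- two_block_matrix(3, 3)
  fit <- nerc(m, k = 2, restarts = 20, seed = 2)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("site", "cluster"))
  expect_equal(nrow(td), 6)
  gl <- glance(fit)
  expect_equal(gl$k, 2L)
  expect_true(gl$converged)
})
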
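#' Convert an occurrence matrix to presence/absence
#'
#' Thresholds a species-by-site count matrix so every positive count becomes 1.
#' Attributes (including the `true_regions` labels attached by
#' [sim_occurrence()]) and dimnames are preserved; the operation is idempotent.
#'
#' @param x A species-by-site occurrence matrix (rows = species, columns =
#'   sites) with non-negative counts.
#' @return A binary matrix of the same shape, with attributes preserved.
#' @seealso [sorensen_dist()]
#' @export
#' @examples
#' m <- matrix(c(0, 3, 1, 7, 0, 2), nrow = 3)
#' as_presence_absence(m)
as_presence_absence <- function(x) {
  x <- validate_occurrence(x)
  out <- x
  out[] <- as.integer(x > 0)
  out
}

#' Sorensen (Dice) dissimilarity between sites
#'
#' Computes pairwise Sorensen dissimilarities `1 - 2a / (2a + b + c)` between
#' the site columns of an occurrence matrix, where `a` is the number of species
#' shared by the two sites and `b`, `c` the numbers unique to each. Counts are
#' reduced to presence/absence first, so abundance information is discarded by
#' construction.
#'
#' @param x A species-by-site occurrence matrix (counts or binary). Every site
#'   must contain at least one species; an all-empty site is an error because
#'   its dissimilarity to anything is undefined.
#' @return A [stats::dist] object over sites, with values in `[0, 1]`.
#' @export
#' @examples
#' m <- matrix(c(1, 1, 1, 0, 0, 1, 1, 1), nrow = 4,
#'             dimnames = list(paste0("sp", 1:4), c("A", "B")))
#' sorensen_dist(m)  # a = 2, b = 1, c = 1 -> 1/3
sorensen_dist <- function(x) {
  x <- as_presence_absence(x)
  rich <- colSums(x)
  if (any(rich == 0)) {
    stop("site(s) with no species present: ",
         paste(colnames(x)[rich == 0], collapse = ", "),
         " (Sorensen dissimilarity is undefined for empty sites)")
  }
  shared <- crossprod(x)            # a_ij: species present in both sites
  denom <- outer(rich, rich, "+")   # 2a + b + c
  d <- 1 - 2 * shared / denom
  diag(d) <- 0
  stats::as.dist(d)
}

#' Validate and coerce a dissimilarity input
#'
#' Accepts a `dist` object or a square numeric matrix and returns a validated
#' square matrix with zero diagonal. Asymmetries larger than `tol` are
#' rejected rather than averaged.
#'
#' @param d A `dist` object or square numeric matrix.
#' @param tol Largest tolerated `|d[i,j] - d[j,i]|`.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
as_dissimilarity_matrix <- function(d, tol = 1e-9) {
  if (inherits(d, "dist")) {
    m <- as.matrix(d)
  } else if (is.matrix(d) && is.numeric(d)) {
    if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
    m <- d
  } else {
    stop("`d` must be a 'dist' object or a square numeric matrix")
  }
  if (anyNA(m)) stop("dissimilarity matrix contains missing values")
  if (max(abs(m - t(m))) > tol) {
    stop("dissimilarity matrix is asymmetric beyond tolerance ", tol)
  }
  if (max(abs(diag(m))) > tol) stop("dissimilarity matrix diagonal must be zero")
  m <- (m + t(m)) / 2   # remove sub-tolerance asymmetry
  diag(m) <- 0
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("s", seq_len(nrow(m)))
  }
  m
}

validate_occurrence <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("occurrence data must be a numeric species-by-site matrix")
  }
  if (any(x < 0)) stop("occurrence counts must be non-negative")
  x
}

#' Read an occurrence matrix from CSV/TSV
#'
#' Expects the first column to hold species identifiers and the header row to
#' hold site identifiers; cells are non-negative integer counts.
#'
#' @param path Path to a CSV (or TSV, with `sep = "\t"`) file.
#' @param sep Field separator.
#' @return A species-by-site integer matrix with dimnames.
#' @export
read_occurrence <- function(path, sep = ",") {
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "integer"
  validate_occurrence(m)
  if (any(colSums(m) == 0)) stop("occurrence file contains an all-zero site column")
  m
}

#' Write an occurrence matrix to CSV
#'
#' @param x Species-by-site matrix.
#' @param path Output path.
#' @export
write_occurrence <- function(x, path) {
  x <- validate_occurrence(x)
  df <- data.frame(species = rownames(x), x, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dissimilarity matrix from CSV
#'
#' Accepts either a square matrix with matching row/column headers (first
#' column = site ids) or a headerless strict lower triangle (line `i` holding
#' the `i` distances to the preceding sites), which is mirrored to a full
#' symmetric matrix. Asymmetric square input beyond a `1e-9` tolerance is
#' rejected.
#'
#' @param path Path to the CSV file.
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
read_dissimilarity <- function(path) {
  first <- strsplit(readLines(path, n = 1), ",")[[1]]
  numeric_first <- !anyNA(suppressWarnings(as.numeric(first)))
  if (numeric_first) {
    rows <- lapply(strsplit(readLines(path), ","), as.numeric)
    n <- length(rows) + 1
    if (!all(lengths(rows) == seq_len(n - 1))) {
      stop("lower-triangle input must have rows of lengths 1, 2, ..., n-1")
    }
    m <- matrix(0, n, n)
    for (i in 2:n) m[i, seq_len(i - 1)] <- rows[[i - 1]]
    m <- m + t(m)
    rownames(m) <- colnames(m) <- paste0("s", seq_len(n))
    m
  } else {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
    as_dissimilarity_matrix(m)
  }
}

#' Write a dissimilarity matrix to CSV (square form)
#'
#' @param d A `dist` object or square matrix.
#' @param path Output path.
#' @export
write_dissimilarity <- function(d, path) {
  m <- as_dissimilarity_matrix(d)
  df <- data.frame(site = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
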
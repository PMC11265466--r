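#' 2 x 2 contingency table for a condition pair
#'
#' @param n11 subjects with both conditions.
#' @param n10 subjects with the first only.
#' @param n01 subjects with the second only.
#' @param n00 subjects with neither.
#' @return an object of class `pair_table` (a named numeric vector with
#'   `n11`, `n10`, `n01`, `n00`, `N`).
#' @export
pair_table <- function(n11, n10, n01, n00) {
  v <- c(n11 = n11, n10 = n10, n01 = n01, n00 = n00)
  if (any(v < 0)) stop("contingency cells must be non-negative")
  structure(c(v, N = sum(v)), class = "pair_table")
}

# contingency table of pair (i, j) from co-occurrence counts
pair_table_from_counts <- function(counts, i, j) {
  n11 <- unname(counts$joint[i, j])
  n10 <- unname(counts$marginal[i]) - n11
  n01 <- unname(counts$marginal[j]) - n11
  n00 <- counts$n_subjects - n11 - n10 - n01
  pair_table(n11, n10, n01, n00)
}

#' Pairwise association measures for binary conditions
#'
#' Five weights describing the strength of association in a 2 x 2 table
#' with cells `n11, n10, n01, n00` and total `N`:
#' \describe{
#'   \item{`odds_ratio()`}{`(n11 * n00) / (n10 * n01)`. When any cell is
#'     zero the Haldane--Anscombe correction (`zero_cell = "haldane"`,
#'     the default) adds 0.5 to all four cells and flags the value;
#'     `zero_cell = "error"` fails instead.}
#'   \item{`lift()`}{joint proportion over the product of the marginal
#'     proportions, `(n11/N) / ((n11+n10)/N * (n11+n01)/N)`; 1 under
#'     independence.}
#'   \item{`phi_coefficient()`}{the Pearson correlation of the two 0/1
#'     indicators, `(n11*n00 - n10*n01) / sqrt((n11+n10)(n01+n00)(n11+n01)(n10+n00))`.}
#'   \item{`salton_cosine()`}{joint count over the geometric mean of the
#'     marginal counts, `n11 / sqrt((n11+n10)(n11+n01))`; in [0, 1], and
#'     1 exactly when the two conditions always co-occur.}
#' }
#' Measures whose margins make them undefined (a condition absent from, or
#' universal in, the cohort) return `NA` with a warning-free flag handled
#' by [compute_all_weights()].
#'
#' @param t a [pair_table()].
#' @param zero_cell zero-cell policy for the odds ratio.
#' @return a single numeric weight.
#' @examples
#' t <- pair_table(20, 10, 10, 20)
#' odds_ratio(t)       # 4
#' lift(t)             # 4/3
#' phi_coefficient(t)  # 1/3
#' salton_cosine(t)    # 2/3
#' @name association_measures
NULL

#' @rdname association_measures
#' @export
odds_ratio <- function(t, zero_cell = c("haldane", "error")) {
  zero_cell <- match.arg(zero_cell)
  if (any(t[c("n11", "n10", "n01", "n00")] == 0)) {
    if (zero_cell == "error") stop("zero cell in contingency table")
    t <- t + 0.5  # Haldane-Anscombe
  }
  unname((t["n11"] * t["n00"]) / (t["n10"] * t["n01"]))
}

#' @rdname association_measures
#' @export
lift <- function(t) {
  mA <- t["n11"] + t["n10"]
  mB <- t["n11"] + t["n01"]
  if (mA == 0 || mB == 0) return(NA_real_)
  unname((t["n11"] / t["N"]) / ((mA / t["N"]) * (mB / t["N"])))
}

#' @rdname association_measures
#' @export
phi_coefficient <- function(t) {
  m <- c(t["n11"] + t["n10"], t["n01"] + t["n00"],
         t["n11"] + t["n01"], t["n10"] + t["n00"])
  if (any(m == 0)) return(NA_real_)
  unname((t["n11"] * t["n00"] - t["n10"] * t["n01"]) / sqrt(prod(m)))
}

#' @rdname association_measures
#' @export
salton_cosine <- function(t) {
  mA <- t["n11"] + t["n10"]
  mB <- t["n11"] + t["n01"]
  if (mA == 0 || mB == 0) return(NA_real_)
  unname(t["n11"] / sqrt(mA * mB))
}

#' Iterative proportional fitting to unit margins
#'
#' Alternately rescales the rows and the columns of a symmetric
#' non-negative matrix with zero diagonal until every row and column sums
#' to one, then symmetrises the limit by averaging with its transpose
#' (alternating scaling transiently breaks symmetry). Applied to a
#' co-occurrence adjacency matrix this removes the effect of differing
#' condition prevalences; the off-diagonal entries of the result are the
#' normalised joint frequency (NF) weights.
#'
#' IPF is invariant to global rescaling of its input, so the NF weights do
#' not depend on the cohort size.
#'
#' @param M symmetric non-negative matrix with zero diagonal; every row
#'   must contain a positive entry.
#' @param tol convergence tolerance on the maximum absolute deviation of
#'   any row/column sum from 1.
#' @param max_iter maximum number of row+column sweeps.
#' @return the normalised matrix, with attributes `iterations` (sweeps
#'   used) and `max_dev` (final margin deviation).
#' @examples
#' M <- matrix(c(0, 3, 1, 3, 0, 2, 1, 2, 0), 3, 3)
#' rowSums(ipf_normalise(M))
#' @export
ipf_normalise <- function(M, tol = 1e-10, max_iter = 10000L) {
  M <- as.matrix(M)
  if (!isTRUE(all.equal(M, t(M), check.attributes = FALSE)))
    stop("'M' must be symmetric")
  if (any(M < 0)) stop("'M' must be non-negative")
  if (any(abs(diag(M)) > 0)) stop("'M' must have a zero diagonal")
  if (any(rowSums(M) == 0)) stop("every row of 'M' needs a positive entry")
  X <- M
  dev <- Inf
  for (it in seq_len(max_iter)) {
    X <- X / rowSums(X)
    cs <- colSums(X)
    X <- sweep(X, 2L, cs, "/")
    dev <- max(abs(rowSums(X) - 1), abs(colSums(X) - 1))
    if (dev < tol) {
      X <- (X + t(X)) / 2
      attr(X, "iterations") <- it
      attr(X, "max_dev") <- dev
      return(X)
    }
  }
  stop(sprintf(paste0("IPF did not converge in %d sweeps (margin deviation %.3g); ",
                      "the support of 'M' cannot carry unit margins"),
               max_iter, dev))
}

#' Compute all five pairwise weights
#'
#' Evaluates the odds ratio, lift, phi correlation, Salton cosine index and
#' IPF-normalised joint frequency for every unordered pair of conditions.
#' Weights are computed from counts, not proportions. Pairs whose margins
#' leave a measure undefined get `NA` and are flagged; odds ratios that
#' needed the zero-cell correction are flagged too.
#'
#' @param counts a [cooccurrence_counts()] (or a [binary_cohort()], which
#'   is tabulated first).
#' @param zero_cell zero-cell policy for the odds ratio, see
#'   [odds_ratio()].
#' @param ipf_tol,ipf_max_iter convergence controls for [ipf_normalise()].
#' @return a `pair_weights` data frame with one row per unordered pair
#'   `(i < j)`: columns `i`, `j`, `or`, `lift`, `phi`, `sci`, `nf`,
#'   `flag_zero_cell`, `flag_undefined`.
#' @export
compute_all_weights <- function(counts, zero_cell = c("haldane", "error"),
                                ipf_tol = 1e-10, ipf_max_iter = 10000L) {
  if (inherits(counts, "binary_cohort")) counts <- tabulate_cooccurrence(counts)
  stopifnot(inherits(counts, "cooccurrence_counts"))
  zero_cell <- match.arg(zero_cell)
  D <- length(counts$labels)
  nf_mat <- ipf_normalise(counts$joint, tol = ipf_tol, max_iter = ipf_max_iter)
  idx <- which(upper.tri(diag(D)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  n_pairs <- nrow(idx)
  out <- data.frame(i = idx[, 1L], j = idx[, 2L],
                    or = NA_real_, lift = NA_real_, phi = NA_real_,
                    sci = NA_real_, nf = NA_real_,
                    flag_zero_cell = FALSE, flag_undefined = FALSE)
  for (k in seq_len(n_pairs)) {
    i <- out$i[k]; j <- out$j[k]
    t <- pair_table_from_counts(counts, i, j)
    zero <- any(t[c("n11", "n10", "n01", "n00")] == 0)
    out$or[k] <- odds_ratio(t, zero_cell)
    out$lift[k] <- lift(t)
    out$phi[k] <- phi_coefficient(t)
    out$sci[k] <- salton_cosine(t)
    out$nf[k] <- nf_mat[i, j]
    out$flag_zero_cell[k] <- zero
    out$flag_undefined[k] <- anyNA(out[k, measure_names()])
  }
  attr(out, "labels") <- counts$labels
  class(out) <- c("pair_weights", "data.frame")
  out
}
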
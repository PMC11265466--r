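#' Construct a binary cohort
#'
#' A binary cohort is a subjects x conditions indicator matrix: entry
#' `[s, d]` is 1 if subject `s` has condition `d` listed, 0 otherwise.
#'
#' @param indicators matrix (or data frame) of 0/1 values, one row per
#'   subject, one column per condition; column names are the condition
#'   labels (generated as `C1..CD` when absent).
#' @return an object of class `binary_cohort`: the validated integer matrix
#'   with condition labels as column names.
#' @examples
#' x <- binary_cohort(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
#' tabulate_cooccurrence(x)
#' @export
binary_cohort <- function(indicators) {
  if (is.data.frame(indicators)) indicators <- as.matrix(indicators)
  if (!is.matrix(indicators) || nrow(indicators) < 1L)
    stop("'indicators' must be a non-empty matrix of 0/1 values")
  if (ncol(indicators) < 2L)
    stop("a cohort needs at least 2 conditions, got ", ncol(indicators))
  bad <- which(!(indicators %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(indicators)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(indicators)) + 1L
    stop(sprintf("non-binary value %s at row %d, column %d", indicators[bad[1L]], i, j))
  }
  if (is.null(colnames(indicators)))
    colnames(indicators) <- paste0("C", seq_len(ncol(indicators)))
  if (anyDuplicated(colnames(indicators)))
    stop("duplicate condition labels: ",
         paste(unique(colnames(indicators)[duplicated(colnames(indicators))]), collapse = ", "))
  storage.mode(indicators) <- "integer"
  rownames(indicators) <- NULL
  structure(indicators, class = c("binary_cohort", "matrix"))
}

#' Construct co-occurrence counts
#'
#' Bundles the symmetric joint-count matrix (the adjacency matrix of the
#' co-occurrence analysis, with a structurally zero diagonal), the
#' per-condition marginal counts, and the total number of subjects.
#'
#' @param joint D x D symmetric non-negative matrix of pair counts; the
#'   diagonal is forced to zero.
#' @param marginal length-D vector, number of subjects with each condition.
#' @param n_subjects total number of subjects.
#' @return an object of class `cooccurrence_counts` with elements `joint`,
#'   `marginal`, `n_subjects`, `labels`.
#' @export
cooccurrence_counts <- function(joint, marginal, n_subjects) {
  joint <- as.matrix(joint)
  D <- nrow(joint)
  if (ncol(joint) != D) stop("'joint' must be square")
  if (!isTRUE(all.equal(joint, t(joint), check.attributes = FALSE)))
    stop("'joint' must be symmetric")
  if (any(joint < 0)) stop("'joint' must be non-negative")
  diag(joint) <- 0
  if (length(marginal) != D) stop("'marginal' must have one entry per condition")
  if (any(marginal < 0) || any(marginal > n_subjects))
    stop("marginal counts must lie in [0, n_subjects]")
  pmin_marg <- outer(marginal, marginal, pmin)
  if (any(joint > pmin_marg))
    stop("joint counts cannot exceed the smaller marginal of a pair")
  labels <- colnames(joint)
  if (is.null(labels)) labels <- names(marginal)
  if (is.null(labels)) labels <- paste0("C", seq_len(D))
  dimnames(joint) <- list(labels, labels)
  structure(list(joint = joint, marginal = setNames(as.numeric(marginal), labels),
                 n_subjects = as.numeric(n_subjects), labels = labels),
            class = "cooccurrence_counts")
}

#' @export
print.cooccurrence_counts <- function(x, ...) {
  cat("Co-occurrence counts:", length(x$labels), "conditions,",
      format(x$n_subjects, big.mark = ","), "subjects\n")
  invisible(x)
}

#' Tabulate pairwise co-occurrence from a binary cohort
#'
#' Counts, for every unordered pair of conditions, the number of subjects
#' with both, and for every condition the number of subjects with it.
#'
#' @param cohort a [binary_cohort()] (or a plain 0/1 matrix).
#' @return a [cooccurrence_counts()] object.
#' @export
tabulate_cooccurrence <- function(cohort) {
  if (!inherits(cohort, "binary_cohort")) cohort <- binary_cohort(cohort)
  x <- unclass(cohort)
  joint <- crossprod(x)              # t(X) %*% X: diagonal = marginals
  marginal <- diag(joint)
  diag(joint) <- 0
  cooccurrence_counts(joint, marginal, nrow(x))
}

#' Read and write cohorts and count matrices
#'
#' Comma-separated UTF-8 text with a mandatory header row of condition
#' labels is the one supported dialect. `write_counts()` stores the joint
#' matrix with the marginal counts as an extra final row named `_marginal`
#' and the subject total as a final `_n_subjects` row, so that
#' `read_counts(write_counts(x))` is lossless.
#'
#' @param path file path.
#' @param cohort a [binary_cohort()].
#' @param counts a [cooccurrence_counts()].
#' @return `read_cohort()` a `binary_cohort`; `read_counts()` a
#'   `cooccurrence_counts`; the writers return `path` invisibly.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2L) stop("cohort file must have a header row and >= 2 columns")
  binary_cohort(as.matrix(df))
}

#' @rdname cohort_io
#' @export
write_cohort <- function(cohort, path) {
  if (!inherits(cohort, "binary_cohort")) cohort <- binary_cohort(cohort)
  write.csv(as.data.frame(unclass(cohort)), path, row.names = FALSE,
            fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "cooccurrence_counts"))
  m <- rbind(counts$joint, `_marginal` = counts$marginal,
             `_n_subjects` = counts$n_subjects)
  df <- data.frame(row = rownames(m), m, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_counts <- function(path) {
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  rn <- df[[1L]]
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- rn
  i_marg <- match("_marginal", rn)
  i_n <- match("_n_subjects", rn)
  if (is.na(i_marg) || is.na(i_n))
    stop("counts file is missing the _marginal / _n_subjects rows")
  joint <- m[-c(i_marg, i_n), , drop = FALSE]
  if (!isTRUE(all.equal(joint, t(joint), check.attributes = FALSE)))
    stop("joint count matrix read from ", path, " is not symmetric")
  cooccurrence_counts(joint, m[i_marg, ], m[i_n, 1L])
}

#' Bundled reference tables
#'
#' `reference_conditions()` returns the 27 chronic conditions of the
#' bundled death-certificate multimorbidity reference study (women aged
#' 85+, N = 283,195 multimorbid deaths): condition rank (1..27 by
#' descending prevalence), display label, and prevalence in percent.
#' `reference_selection()` returns the study's 56 "top pairs" -- the
#' unordered condition pairs selected as strongly associated (above the
#' 90th weight percentile) by at least one of the five association
#' measures -- as a [selection_matrix()] with one 0/1 flag per measure.
#'
#' @return `reference_conditions()`: a data frame with columns `rank`,
#'   `label`, `prevalence`. `reference_selection()`: a `selection_matrix`.
#' @examples
#' head(reference_conditions())
#' overlap_summary(reference_selection())
#' @export
reference_conditions <- function() {
  df <- read.csv(system.file("extdata", "condition_prevalence.csv",
                             package = "mmnet", mustWork = TRUE),
                 fileEncoding = "UTF-8")
  stopifnot(nrow(df) == 27L, identical(df$rank, 1:27),
            !is.unsorted(rev(df$prevalence)))
  df
}

#' @rdname reference_conditions
#' @export
reference_selection <- function() {
  df <- read.csv(system.file("extdata", "top_pair_selection.csv",
                             package = "mmnet", mustWork = TRUE),
                 fileEncoding = "UTF-8")
  selection_matrix(pairs = df[, c("i", "j")],
                   indicators = as.matrix(df[, c("or", "lift", "phi", "sci", "nf")]),
                   universe_size = 27L * 26L / 2L)
}

#' Construct a selection matrix
#'
#' Records, for each listed unordered condition pair, a 0/1 flag per
#' association measure marking whether the pair was selected as a "top
#' pair" by that measure. Pairs not listed are implicitly unselected by
#' every measure; `universe_size` is the number of candidate pairs
#' D(D-1)/2.
#'
#' @param pairs two-column matrix/data frame of condition ids (`i`, `j`).
#' @param indicators matrix of 0/1 flags, one row per pair, columns in the
#'   fixed measure order `or`, `lift`, `phi`, `sci`, `nf`.
#' @param universe_size total number of candidate pairs.
#' @return an object of class `selection_matrix`: a data frame with columns
#'   `i`, `j` and the five measure flags, plus a `universe_size` attribute.
#' @export
selection_matrix <- function(pairs, indicators, universe_size) {
  pairs <- as.data.frame(pairs)
  names(pairs) <- c("i", "j")
  ind <- as.matrix(indicators)
  if (is.null(colnames(ind))) colnames(ind) <- measure_names()
  stopifnot(identical(colnames(ind), measure_names()),
            nrow(ind) == nrow(pairs), all(ind %in% c(0, 1)))
  swap <- pairs$i > pairs$j
  if (any(swap)) pairs[swap, c("i", "j")] <- pairs[swap, c("j", "i")]
  key <- paste(pairs$i, pairs$j)
  if (anyDuplicated(key)) stop("duplicate pairs: ", key[duplicated(key)][1L])
  if (universe_size < nrow(pairs))
    stop("universe_size smaller than the number of listed pairs")
  structure(cbind(pairs, as.data.frame(ind)),
            universe_size = as.integer(universe_size),
            class = c("selection_matrix", "data.frame"))
}

#' The five association measures, in canonical order
#' @return `c("or", "lift", "phi", "sci", "nf")`
#' @export
measure_names <- function() c("or", "lift", "phi", "sci", "nf")
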
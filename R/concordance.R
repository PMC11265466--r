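#' Cohen's kappa between two top-pair selections
#'
#' Chance-corrected agreement `kappa = (p_o - p_e) / (1 - p_e)` between two
#' binary selections of condition pairs, where `p_o` is the observed
#' proportion of pairs on which the selections agree and `p_e` the
#' agreement expected from the marginal selection rates.
#'
#' The base set over which agreement is evaluated matters. With
#' `base = "union"` (the default) the universe is the pairs selected by at
#' least one measure in the surrounding [selection_matrix()]; with
#' `base = "all_pairs"` it is all D(D-1)/2 candidate pairs, unselected
#' pairs counting as agreeing absences. The two give different values: on
#' the bundled reference selection, OR vs lift gives 0.85 under the union
#' base and about 0.94 under the all-pairs base.
#'
#' @param sel_a,sel_b 0/1 (or logical) vectors over the same universe of
#'   pairs.
#' @param n_universe size of the base set; defaults to `length(sel_a)`.
#'   When larger, the extra pairs are taken as unselected by both.
#' @return kappa, in [-1, 1].
#' @export
cohen_kappa <- function(sel_a, sel_b, n_universe = length(sel_a)) {
  stopifnot(length(sel_a) == length(sel_b), n_universe >= length(sel_a))
  a <- as.logical(sel_a)
  b <- as.logical(sel_b)
  extra <- n_universe - length(a)         # pairs outside the listed set: 0/0
  n11 <- sum(a & b)
  n10 <- sum(a & !b)
  n01 <- sum(!a & b)
  n00 <- sum(!a & !b) + extra
  n <- n_universe
  po <- (n11 + n00) / n
  pe <- ((n11 + n10) / n) * ((n11 + n01) / n) +
        ((n01 + n00) / n) * ((n10 + n00) / n)
  if (pe == 1) {
    if (po == 1) return(1)
    stop("degenerate selections: chance agreement is 1 but selections differ")
  }
  (po - pe) / (1 - pe)
}

#' Cross-measure concordance summary
#'
#' Counts how the five measures' top-pair selections overlap: the number
#' of pairs selected by at least one measure (the union), by all five, and
#' by exactly one (attributed to that measure); per-measure totals; and
#' the 5 x 5 Cohen's kappa matrix.
#'
#' @param sel a [selection_matrix()].
#' @param kappa_base `"union"` (kappa over the pairs selected by at least
#'   one measure; default) or `"all_pairs"` (kappa over all candidate
#'   pairs).
#' @return an object of class `concordance_summary`: list with
#'   `union_count`, `all_five_count`, `exactly_one_total`,
#'   `exactly_one_counts` (per measure), `per_measure_counts`, `kappa`
#'   (5 x 5 matrix), `kappa_base`, `universe_size`.
#' @examples
#' overlap_summary(reference_selection())
#' @export
overlap_summary <- function(sel, kappa_base = c("union", "all_pairs")) {
  stopifnot(inherits(sel, "selection_matrix"))
  kappa_base <- match.arg(kappa_base)
  ind <- as.matrix(sel[, measure_names()])
  n_sel <- rowSums(ind)
  union_count <- sum(n_sel > 0)
  m <- measure_names()
  exactly_one <- setNames(colSums(ind[n_sel == 1L, , drop = FALSE]), m)
  n_univ <- if (kappa_base == "union") union_count else attr(sel, "universe_size")
  kap <- matrix(1, 5, 5, dimnames = list(m, m))
  for (a in 1:4) for (b in (a + 1):5) {
    kap[a, b] <- kap[b, a] <- cohen_kappa(ind[, a], ind[, b], n_univ)
  }
  structure(list(union_count = union_count,
                 all_five_count = sum(n_sel == 5L),
                 exactly_one_total = sum(n_sel == 1L),
                 exactly_one_counts = exactly_one,
                 per_measure_counts = colSums(ind),
                 by_k = tabulate(n_sel, nbins = 5L),
                 kappa = kap, kappa_base = kappa_base,
                 universe_size = attr(sel, "universe_size")),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("Top pairs: %d selected by >=1 measure (of %d candidates), %d by all five, %d by exactly one\n",
              x$union_count, x$universe_size, x$all_five_count, x$exactly_one_total))
  one <- x$exactly_one_counts[x$exactly_one_counts > 0]
  if (length(one))
    cat("  exactly-one by measure:",
        paste(sprintf("%s %d", toupper(names(one)), one), collapse = ", "), "\n")
  cat("Per-measure counts:",
      paste(sprintf("%s %d", toupper(measure_names()), x$per_measure_counts), collapse = ", "), "\n")
  cat(sprintf("Cohen's kappa (base: %s):\n", x$kappa_base))
  print(round(x$kappa, 2))
  invisible(x)
}

#' Contribution of a prevalence group to the top pairs
#'
#' Counts, for each measure, how often the conditions with the given
#' prevalence ranks contributed to its top pairs. With `per = "pair"`
#' (the default) a selected pair is counted once if at least one member
#' is in the rank set; with `per = "incidence"` each in-set member counts
#' separately (a pair with both members in the set counts twice).
#'
#' @param sel a [selection_matrix()] whose pair ids are prevalence ranks.
#' @param rank_set integer vector of prevalence ranks.
#' @param per counting convention, `"pair"` or `"incidence"`.
#' @return named integer vector, one count per measure.
#' @export
prevalence_group_contributions <- function(sel, rank_set,
                                           per = c("pair", "incidence")) {
  stopifnot(inherits(sel, "selection_matrix"))
  per <- match.arg(per)
  ind <- as.matrix(sel[, measure_names()])
  hits <- (sel$i %in% rank_set) + (sel$j %in% rank_set)
  if (per == "pair") hits <- as.integer(hits > 0)
  setNames(as.integer(colSums(ind * hits)), measure_names())
}

#' Conditions that did not join a community
#'
#' The conditions left in singleton communities of a partition (including
#' every degree-0 node of the thresholded network), annotated with their
#' prevalence rank where the node ids are ranks.
#'
#' @param partition a `community_partition` from [leiden_partition()].
#' @return data frame with columns `node` and `rank` (NA when the node id
#'   is not numeric).
#' @export
unjoined_conditions <- function(partition) {
  stopifnot(inherits(partition, "community_partition"))
  nodes <- partition$unjoined
  data.frame(node = nodes,
             rank = suppressWarnings(as.integer(nodes)),
             stringsAsFactors = FALSE)
}

#' Assemble the cross-measure analysis report
#'
#' Collects the selection matrix, the concordance summary, the community
#' structure and the top-3 centrality tables of each measure's network
#' into one machine-readable list (serialisable to JSON) that mirrors the
#' printed outputs of the pipeline.
#'
#' @param weights a `pair_weights` data frame.
#' @param selection a [selection_matrix()].
#' @param partitions named list of `community_partition`s, one per measure.
#' @param centralities named list of [centrality_table()]s, one per
#'   measure.
#' @param kappa_base base set for kappa, see [overlap_summary()].
#' @return a list of class `mmnet_report`.
#' @export
build_report <- function(weights, selection, partitions, centralities,
                         kappa_base = "union") {
  for (nm in c("weights", "selection", "partitions", "centralities")) {
    if (is.null(get(nm))) stop("missing input: ", nm)
  }
  conc <- overlap_summary(selection, kappa_base)
  per_measure <- lapply(measure_names(), function(m) {
    p <- partitions[[m]]
    ct <- centralities[[m]]
    list(measure = m,
         n_communities = p$n_communities,
         modularity = p$Q,
         unjoined = unjoined_conditions(p)$node,
         top3 = lapply(top_k_centrality(ct, 3L), function(d)
           list(node = d$node, value = d$value, tied = d$tied[1L])))
  })
  names(per_measure) <- measure_names()
  structure(list(
    n_pairs = nrow(weights),
    selection = as.data.frame(selection),
    concordance = list(
      union_count = conc$union_count,
      all_five_count = conc$all_five_count,
      exactly_one_counts = as.list(conc$exactly_one_counts),
      per_measure_counts = as.list(conc$per_measure_counts),
      kappa = round(conc$kappa, 2),   # rounding at output only
      kappa_base = conc$kappa_base),
    networks = per_measure), class = "mmnet_report")
}
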
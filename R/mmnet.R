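#' Fit a multi-weight multimorbidity network analysis
#'
#' Runs the whole pipeline on a binary cohort or a co-occurrence count
#' matrix: computes the five pairwise association weights (odds ratio,
#' lift, phi correlation, Salton cosine index, IPF-normalised joint
#' frequency), keeps the pairs above the `percentile`-th percentile of
#' each weight distribution, builds the five weighted networks, detects
#' communities by Leiden clustering at resolution `gamma`, computes
#' weighted degree/closeness/betweenness centralities, and summarises the
#' cross-measure concordance (overlap counts and Cohen's kappa).
#'
#' @param x a [binary_cohort()] (or plain 0/1 subjects x conditions
#'   matrix) or a [cooccurrence_counts()].
#' @param percentile selection percentile for top pairs (default 90).
#' @param gamma Leiden/modularity resolution parameter (default 1).
#' @param seed integer seed for the (restarted) community detection.
#' @param n_restarts Leiden restarts per network (default 10).
#' @param zero_cell zero-cell policy for the odds ratio
#'   ([odds_ratio()]).
#' @param transform distance transform for closeness/betweenness
#'   ([centrality_table()]).
#' @param kappa_base base set for Cohen's kappa ([overlap_summary()]).
#' @param prevalence optional per-condition prevalences (percent) used to
#'   annotate the networks; computed from the cohort when `x` is one.
#' @return an object of class `mmnet`: list with elements `counts`,
#'   `weights`, `selection`, `networks`, `partitions`, `centralities`,
#'   `concordance`, `report` and `call`.
#' @examples
#' co <- generate_cohort(2000, prevalence = c(A = 30, B = 25, C = 20, D = 15,
#'                                            E = 10, F = 8, G = 6, H = 5),
#'                       seed = 1)
#' fit <- mmnet(co, seed = 1)
#' fit
#' coef(fit)[1:3, ]
#' @export
mmnet <- function(x, percentile = 90, gamma = 1, seed = 1L, n_restarts = 10L,
                  zero_cell = "haldane", transform = "inverse",
                  kappa_base = "union", prevalence = NULL) {
  counts <- if (inherits(x, "cooccurrence_counts")) x else {
    cohort <- if (inherits(x, "binary_cohort")) x else binary_cohort(x)
    if (is.null(prevalence)) prevalence <- 100 * colMeans(cohort)
    tabulate_cooccurrence(cohort)
  }
  if (is.null(prevalence) && !is.null(counts$n_subjects))
    prevalence <- 100 * counts$marginal / counts$n_subjects

  weights <- compute_all_weights(counts, zero_cell = zero_cell)
  selection <- select_all_measures(weights, percentile = percentile)

  networks <- partitions <- centralities <- setNames(
    vector("list", 5L), measure_names())
  for (m in measure_names()) {
    sel_m <- select_top_pairs(weights, m, percentile = percentile)
    g <- build_network(weights, sel_m, m, labels = counts$labels,
                       prevalence = prevalence)
    networks[[m]] <- g
    partitions[[m]] <- leiden_partition(g, gamma = gamma, seed = seed,
                                        n_restarts = n_restarts)
    centralities[[m]] <- centrality_table(g, transform = transform)
  }
  concordance <- overlap_summary(selection, kappa_base)
  report <- build_report(weights, selection, partitions, centralities,
                         kappa_base)
  structure(list(counts = counts, weights = weights, selection = selection,
                 networks = networks, partitions = partitions,
                 centralities = centralities, concordance = concordance,
                 report = report, percentile = percentile, gamma = gamma,
                 call = match.call()),
            class = "mmnet")
}

#' @export
print.mmnet <- function(x, ...) {
  cat("Multi-weight multimorbidity network analysis\n")
  cat(sprintf("  %d conditions, %s subjects, %d candidate pairs, top %g%% kept per measure\n",
              length(x$counts$labels),
              format(x$counts$n_subjects, big.mark = ","),
              nrow(x$weights), 100 - x$percentile))
  cat(sprintf("  top pairs: union %d, all five %d\n",
              x$concordance$union_count, x$concordance$all_five_count))
  comms <- vapply(x$partitions, function(p) p$n_communities, integer(1))
  cat("  communities:",
      paste(sprintf("%s %d", toupper(names(comms)), comms), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mmnet <- function(object, ...) {
  structure(list(fit = object), class = "summary.mmnet")
}

#' @export
print.summary.mmnet <- function(x, ...) {
  fit <- x$fit
  print(fit)
  cat("\n")
  print(fit$concordance)
  cat("\nPer-measure networks:\n")
  for (m in measure_names()) {
    p <- fit$partitions[[m]]
    un <- p$unjoined
    cat(sprintf("  %-4s %2d edges, %d communities (Q = %.3f)%s\n",
                toupper(m), igraph::ecount(fit$networks[[m]]),
                p$n_communities,
                p$Q,
                if (length(un)) paste0(", unjoined: ", paste(un, collapse = " ")) else ""))
  }
  invisible(x)
}

#' @describeIn mmnet the pair weight table (one row per unordered pair,
#'   the five weights as columns).
#' @param object,... an `mmnet` fit; further arguments ignored.
#' @export
coef.mmnet <- function(object, ...) object$weights

#' @describeIn mmnet plot one measure's thresholded network (edge width
#'   proportional to weight, colours by community).
#' @param measure which network to plot.
#' @export
plot.mmnet <- function(x, measure = "phi", ...) {
  measure <- match.arg(measure, measure_names())
  g <- x$networks[[measure]]
  memb <- x$partitions[[measure]]$membership
  w <- edge_weights(g)
  ew <- if (length(w)) 1 + 3 * w / max(w) else numeric()
  plot(g, vertex.color = memb, edge.width = ew,
       main = paste("Top-pair network:", toupper(measure)), ...)
  invisible(x)
}
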
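#' Select the top pairs of a weight distribution
#'
#' A pair is a "top pair" for a measure when its weight lies strictly above
#' the chosen empirical percentile (default the 90th) of all defined
#' weights for that measure. The percentile uses the linear-interpolation
#' quantile convention (`stats::quantile` type 7); undefined (`NA`)
#' weights are excluded from both the percentile and the selection.
#' Because the rule is a rank rule it is invariant under any strictly
#' increasing transform of the weights.
#'
#' With all 351 pairs of 27 conditions defined and distinct, the rule
#' keeps exactly 35 pairs. Ties at the threshold are dropped (strictly
#' "above"); if every weight is equal nothing is selected and a warning is
#' emitted.
#'
#' @param weights a `pair_weights` data frame from [compute_all_weights()].
#' @param measure one of [measure_names()].
#' @param percentile percentile in (0, 100), default 90.
#' @param strict select strictly above the threshold (default) or at and
#'   above it.
#' @return logical vector, one entry per row of `weights` (`FALSE` for
#'   undefined weights), with the threshold as attribute `threshold`.
#' @export
select_top_pairs <- function(weights, measure, percentile = 90, strict = TRUE) {
  measure <- match.arg(measure, measure_names())
  w <- weights[[measure]]
  ok <- !is.na(w)
  if (sum(ok) < 10L) stop("need at least 10 defined weights for '", measure, "'")
  thr <- unname(quantile(w[ok], percentile / 100, type = 7))
  sel <- ok & (if (strict) w > thr else w >= thr)
  if (!any(sel)) warning("no pair above the ", percentile, "th percentile for '", measure, "'")
  attr(sel, "threshold") <- thr
  sel
}

#' Selection matrix across all five measures
#'
#' Applies [select_top_pairs()] per measure and assembles the result as a
#' [selection_matrix()] listing the pairs selected by at least one measure.
#'
#' @inheritParams select_top_pairs
#' @return a `selection_matrix`.
#' @export
select_all_measures <- function(weights, percentile = 90, strict = TRUE) {
  sel <- sapply(measure_names(), function(m)
    as.integer(select_top_pairs(weights, m, percentile, strict)))
  keep <- rowSums(sel) > 0
  selection_matrix(weights[keep, c("i", "j")], sel[keep, , drop = FALSE],
                   universe_size = nrow(weights))
}

#' Build the weighted network of a measure
#'
#' Nodes are all conditions (isolated nodes are retained so that community
#' detection can report non-joining conditions); edges are the pairs
#' selected for the measure, weighted by that measure's value.
#'
#' @param weights a `pair_weights` data frame.
#' @param selection logical/0-1 vector over the rows of `weights` (e.g.
#'   from [select_top_pairs()]).
#' @param measure one of [measure_names()].
#' @param labels optional node labels (defaults to the labels attached to
#'   `weights`, else `C1..CD`).
#' @param prevalence optional per-node prevalence (stored as a node
#'   attribute, e.g. for export).
#' @return an `igraph` undirected graph with edge attribute `weight`,
#'   graph attribute `measure`, and node attributes `name` (condition id),
#'   `label`, and optionally `prevalence`.
#' @export
build_network <- function(weights, selection, measure, labels = NULL,
                          prevalence = NULL) {
  measure <- match.arg(measure, measure_names())
  stopifnot(length(selection) == nrow(weights))
  D <- max(weights$j)
  if (is.null(labels)) labels <- attr(weights, "labels")
  if (is.null(labels)) labels <- paste0("C", seq_len(D))
  sel <- which(as.logical(selection))
  edges <- rbind(weights$i[sel], weights$j[sel])
  g <- igraph::make_empty_graph(n = D, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(D)))
  g <- igraph::set_vertex_attr(g, "label", value = as.character(labels))
  if (!is.null(prevalence))
    g <- igraph::set_vertex_attr(g, "prevalence", value = prevalence)
  if (length(sel))
    g <- igraph::add_edges(g, as.character(as.vector(edges)),
                           weight = weights[[measure]][sel])
  g <- igraph::set_graph_attr(g, "measure", measure)
  g
}

#' Export a network to GraphML or an edge-list
#'
#' GraphML keeps node labels, prevalences and edge weights and round-trips
#' through `igraph::read_graph()`. The `edgelist` format is plain
#' tab-separated text `from to weight` with a header line.
#'
#' @param network an `igraph` graph from [build_network()].
#' @param path output file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return `path`, invisibly.
#' @export
export_graph <- function(network, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    df <- data.frame(from = el[, 1L], to = el[, 2L],
                     weight = if (igraph::ecount(network))
                       igraph::E(network)$weight else numeric())
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Node strengths (weighted degrees) of a network
#'
#' @param network an `igraph` graph with a `weight` edge attribute.
#' @return named numeric vector: the sum of incident edge weights per node.
#' @export
node_strengths <- function(network) {
  igraph::strength(network, weights = edge_weights(network))
}

edge_weights <- function(network) {
  if (igraph::ecount(network) == 0) return(numeric())
  w <- igraph::E(network)$weight
  if (is.null(w)) rep(1, igraph::ecount(network)) else w
}
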
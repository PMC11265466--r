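#' Modularity of a partition
#'
#' Weighted Newman--Girvan modularity with a resolution parameter:
#' \deqn{Q = \frac{1}{2m} \sum_{ij} \left[A_{ij} - \gamma \frac{K_i K_j}{2m}\right] \delta(c_i, c_j)}
#' where \eqn{A} is the weighted adjacency matrix, \eqn{K_i} the strength
#' (sum of incident weights) of node \eqn{i}, \eqn{2m = \sum_{ij} A_{ij}}
#' the total weight, \eqn{\gamma} the resolution (larger values favour
#' more, smaller communities), and \eqn{\delta = 1} when two nodes share a
#' community. Q is invariant to community relabelling and to uniform
#' rescaling of the edge weights.
#'
#' @param network an `igraph` graph with a `weight` edge attribute.
#' @param membership community label per node (any atomic vector).
#' @param gamma resolution parameter, > 0 (default 1).
#' @return the modularity Q.
#' @examples
#' g <- igraph::make_full_graph(3)
#' igraph::E(g)$weight <- 1
#' modularity_q(g, c(1, 2, 3))  # -1/3
#' @export
modularity_q <- function(network, membership, gamma = 1) {
  stopifnot(gamma > 0)
  n <- igraph::vcount(network)
  if (length(membership) != n) stop("partition must cover all nodes")
  A <- as.matrix(igraph::as_adjacency_matrix(
    network, attr = if (igraph::ecount(network) &&
                        !is.null(igraph::E(network)$weight)) "weight" else NULL,
    sparse = FALSE))
  two_m <- sum(A)
  if (two_m == 0) stop("modularity is undefined for a network with no edges")
  K <- rowSums(A)
  same <- outer(membership, membership, "==")
  sum((A - gamma * outer(K, K) / two_m) * same) / two_m
}

#' Leiden community detection
#'
#' Modularity-maximising Leiden clustering (greedy local moving with
#' community refinement and aggregation, iterated until no further gain)
#' at resolution `gamma`, restarted `n_restarts` times from different
#' seeded RNG states; the partition with the highest modularity (as
#' recomputed by [modularity_q()]) is returned. Deterministic given
#' `seed`. Isolated nodes always come out as singleton communities.
#'
#' @param network an `igraph` graph with `weight` edge attribute and at
#'   least one edge.
#' @param gamma resolution parameter (default 1).
#' @param seed integer seed governing all restarts.
#' @param n_restarts number of seeded restarts (default 10).
#' @return an object of class `community_partition`: list with
#'   `membership` (integer labels, named by node), `Q`, `n_communities`,
#'   `sizes`, `unjoined` (names of nodes in singleton communities),
#'   `gamma`.
#' @export
leiden_partition <- function(network, gamma = 1, seed = 1L, n_restarts = 10L) {
  if (igraph::ecount(network) == 0)
    stop("community detection needs a network with at least one edge")
  w <- edge_weights(network)
  best <- NULL
  best_q <- -Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    cl <- igraph::cluster_leiden(network, objective_function = "modularity",
                                 resolution = gamma, weights = w,
                                 n_iterations = 10L)
    memb <- igraph::membership(cl)
    q <- modularity_q(network, as.integer(memb), gamma)
    if (q > best_q) {
      best_q <- q
      best <- as.integer(memb)
    }
  }
  names(best) <- igraph::V(network)$name
  sizes <- table(best)
  singletons <- names(best)[best %in% as.integer(names(sizes)[sizes == 1L])]
  structure(list(membership = best, Q = best_q,
                 n_communities = length(sizes),
                 sizes = as.integer(sizes), unjoined = singletons,
                 gamma = gamma),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("Partition: %d communities, Q = %.4f (gamma = %g)\n",
              x$n_communities, x$Q, x$gamma))
  if (length(x$unjoined))
    cat("Unjoined (singleton) nodes:", paste(x$unjoined, collapse = ", "), "\n")
  invisible(x)
}

# association weight -> path length; strong ties are short distances
distance_transform <- function(w, transform = c("inverse", "identity")) {
  transform <- match.arg(transform)
  if (transform == "inverse") 1 / w else w
}

#' Weighted centrality statistics
#'
#' For every node: the degree (strength: sum of incident association
#' weights), the closeness (reciprocal of the summed shortest-path
#' lengths to the other reachable nodes), and the betweenness (sum over
#' other node pairs of the proportion of shortest paths through the node).
#' Shortest paths run on transformed edge lengths: the default
#' `transform = "inverse"` maps an association weight `w` to a length
#' `1/w`, so strongly associated conditions are close; `"identity"`
#' treats weights directly as lengths (the convention of tools that read
#' weights as costs). Closeness sums only over the node's connected
#' component (its size is reported); isolated nodes get closeness 0 by
#' convention. Disconnected pairs contribute nothing to betweenness.
#'
#' @param network an `igraph` graph with a `weight` edge attribute.
#' @param transform `"inverse"` (default) or `"identity"`.
#' @return a `centrality_table` data frame: `node`, `label`, `degree`,
#'   `closeness`, `betweenness`, `component_size`, with the transform as
#'   an attribute.
#' @export
centrality_table <- function(network, transform = c("inverse", "identity")) {
  transform <- match.arg(transform)
  n <- igraph::vcount(network)
  w <- edge_weights(network)
  len <- distance_transform(w, transform)
  deg <- igraph::strength(network, weights = w)
  comp <- igraph::components(network)
  csize <- comp$csize[comp$membership]
  if (igraph::ecount(network)) {
    d <- igraph::distances(network, weights = len)
    closeness <- vapply(seq_len(n), function(v) {
      s <- sum(d[v, is.finite(d[v, ]) & seq_len(n) != v])
      if (s > 0) 1 / s else 0
    }, numeric(1))
    btw <- igraph::betweenness(network, weights = len, directed = FALSE)
  } else {
    closeness <- rep(0, n)
    btw <- rep(0, n)
  }
  labels <- igraph::V(network)$label
  if (is.null(labels)) labels <- igraph::V(network)$name
  out <- data.frame(node = igraph::V(network)$name, label = labels,
                    degree = unname(deg), closeness = unname(closeness),
                    betweenness = unname(btw), component_size = csize,
                    stringsAsFactors = FALSE)
  attr(out, "transform") <- transform
  class(out) <- c("centrality_table", "data.frame")
  out
}

#' Top-k nodes per centrality statistic
#'
#' The `k` nodes with the highest degree, closeness and betweenness. Ties
#' are broken by prevalence rank (ascending numeric node id), and a tie
#' crossing the k-th place is flagged.
#'
#' @param table a [centrality_table()].
#' @param k how many nodes per statistic (default 3).
#' @return named list with one data frame per statistic (`node`, `label`,
#'   `value`, `tied`).
#' @export
top_k_centrality <- function(table, k = 3L) {
  stopifnot(nrow(table) > 0L)
  stats <- c("degree", "closeness", "betweenness")
  out <- lapply(stats, function(s) {
    v <- table[[s]]
    id <- suppressWarnings(as.numeric(table$node))
    if (anyNA(id)) id <- seq_len(nrow(table))
    ord <- order(-v, id)
    top <- head(ord, k)
    tied <- length(v) > k && v[ord[k]] == v[ord[k + 1L]]
    data.frame(node = table$node[top], label = table$label[top],
               value = v[top], tied = tied, stringsAsFactors = FALSE)
  })
  names(out) <- stats
  out
}
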
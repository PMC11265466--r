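# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: plain loops, exhaustive enumeration, and
# igraph only where igraph is NOT the implementation under test.

# co-occurrence counting by explicit double loop over condition pairs
oracle_cooccurrence <- function(x) {
  D <- ncol(x)
  joint <- matrix(0, D, D)
  for (i in seq_len(D)) {
    for (j in seq_len(D)) {
      if (i != j) joint[i, j] <- sum(x[, i] == 1 & x[, j] == 1)
    }
  }
  list(joint = joint, marginal = colSums(x))
}

# long-run IPF without convergence tests: fixed number of sweeps
oracle_ipf <- function(M, sweeps = 10000L) {
  X <- M
  for (s in seq_len(sweeps)) {
    for (i in seq_len(nrow(X))) X[i, ] <- X[i, ] / sum(X[i, ])
    for (j in seq_len(ncol(X))) X[, j] <- X[, j] / sum(X[, j])
  }
  (X + t(X)) / 2
}

# random connected-ish weighted graph as a weighted adjacency matrix
random_weighted_graph <- function(n, p = 0.5, wmin = 0.2, wmax = 2) {
  repeat {
    A <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (runif(1) < p) A[i, j] <- A[j, i] <- runif(1, wmin, wmax)
      }
    }
    if (sum(A) > 0) return(A)
  }
}

graph_from_adj <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE)
  igraph::set_vertex_attr(g, "name", value = as.character(seq_len(nrow(A))))
}

# enumerate all simple paths between s and t over adjacency support
all_simple_paths_brute <- function(A, s, t) {
  n <- nrow(A)
  out <- list()
  walk <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      out[[length(out) + 1L]] <<- path
      return(invisible())
    }
    for (u in seq_len(n)) {
      if (A[v, u] > 0 && !(u %in% path)) walk(c(path, u))
    }
  }
  walk(s)
  out
}

# all-pairs shortest paths, path counts and pass-through credit by
# exhaustive path enumeration on transformed lengths L (L[i,j] = 0: no edge)
oracle_paths <- function(L, tol = 1e-9) {
  n <- nrow(L)
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_brute(L, s, t)
      if (!length(paths)) next
      lens <- vapply(paths, function(p)
        sum(L[cbind(p[-length(p)], p[-1L])]), numeric(1))
      dmin <- min(lens)
      dist[s, t] <- dist[t, s] <- dmin
      short <- paths[lens <= dmin + tol]
      inner <- unlist(lapply(short, function(p) p[-c(1L, length(p))]))
      if (length(inner)) {
        tab <- table(inner)
        idx <- as.integer(names(tab))
        btw[idx] <- btw[idx] + as.numeric(tab) / length(short)
      }
    }
  }
  closeness <- vapply(seq_len(n), function(v) {
    d <- dist[v, -v]
    d <- d[is.finite(d)]
    if (length(d) && sum(d) > 0) 1 / sum(d) else 0
  }, numeric(1))
  list(dist = dist, betweenness = btw, closeness = closeness)
}

# all set partitions of n elements as restricted-growth strings
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, mx) {
    k <- length(labels)
    if (k == n) {
      out[[length(out) + 1L]] <<- labels
      return(invisible())
    }
    for (v in seq_len(mx + 1L)) grow(c(labels, v), max(mx, v))
  }
  grow(1L, 1L)
  out
}

# exhaustive maximum-modularity partition, scored by igraph::modularity
# (independent of both modularity_q and leiden_partition)
oracle_best_partition <- function(g, gamma = 1) {
  n <- igraph::vcount(g)
  w <- igraph::E(g)$weight
  best_q <- -Inf
  for (p in all_partitions(n)) {
    q <- igraph::modularity(g, p, weights = w, resolution = gamma)
    if (q > best_q) best_q <- q
  }
  best_q
}

make_fit_cohort <- function(n = 1500, seed = 42) {
  generate_cohort(n, prevalence = c(A = 35, B = 30, C = 25, D = 20, E = 15,
                                    F = 12, G = 10, H = 8, I = 6, J = 5),
                  structure = planted_structure(rep(1:2, 5), rho_within = 0.45,
                                                rho_between = 0),
                  seed = seed)
}
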
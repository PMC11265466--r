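test_that("single-pair measures match hand computations", {
  ind <- pair_table(10, 10, 10, 10)
  t1 <- pair_table(20, 10, 10, 20)
  expect_equal(odds_ratio(ind), 1)
  expect_equal(lift(ind), 1)
  expect_equal(phi_coefficient(ind), 0)

  expect_equal(odds_ratio(t1), 4)
  expect_equal(lift(t1), 4 / 3)
  expect_equal(phi_coefficient(t1), 300 / 900)
  expect_equal(salton_cosine(t1), 20 / sqrt(900))
})

test_that("zero cells fall back to the Haldane-Anscombe correction", {
  t0 <- pair_table(5, 0, 3, 12)
  expect_equal(odds_ratio(t0), (5.5 * 12.5) / (0.5 * 3.5))
  expect_error(odds_ratio(t0, zero_cell = "error"), "zero cell")
})

test_that("degenerate margins are undefined or zero as appropriate", {
  none <- pair_table(0, 5, 3, 12)          # never co-occur
  expect_equal(lift(none), 0)
  expect_equal(salton_cosine(none), 0)
  absent <- pair_table(0, 0, 4, 6)         # first condition absent
  expect_true(is.na(lift(absent)))
  expect_true(is.na(phi_coefficient(absent)))
  expect_true(is.na(salton_cosine(absent)))
  always <- pair_table(3, 2, 0, 0)         # second margin degenerate
  expect_true(is.na(phi_coefficient(always)))
})

test_that("SCI stays in [0, 1] and is 1 iff the conditions coincide", {
  set.seed(21)
  for (k in 1:50) {
    t <- pair_table(sample(0:20, 1), sample(0:20, 1),
                    sample(0:20, 1), sample(1:20, 1))
    s <- salton_cosine(t)
    if (is.na(s)) next
    expect_gte(s, 0)
    expect_lte(s, 1)
    if (t[["n10"]] == 0 && t[["n01"]] == 0 && t[["n11"]] > 0) expect_equal(s, 1)
    if (s == 1) expect_true(t[["n10"]] == 0 && t[["n01"]] == 0)
  }
  expect_equal(salton_cosine(pair_table(7, 0, 0, 3)), 1)
})

test_that("phi equals the Pearson correlation of the indicator vectors", {
  set.seed(8)
  for (k in 1:20) {
    n <- 60
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    t <- pair_table(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b))
    expect_equal(phi_coefficient(t), cor(a, b))
  }
})

test_that("IPF reaches unit margins and matches a long-run scaling oracle", {
  # 2x2: any positive symmetric matrix normalises to the exchange matrix
  expect_equal(unclass(ipf_normalise(matrix(c(0, 3.7, 3.7, 0), 2, 2))),
               matrix(c(0, 1, 1, 0), 2, 2), ignore_attr = TRUE)

  # 3x3 all-ones off-diagonal: symmetry forces 0.5 everywhere off-diagonal
  M3 <- matrix(1, 3, 3); diag(M3) <- 0
  X3 <- ipf_normalise(M3)
  expect_equal(unclass(X3), matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3, 3),
               ignore_attr = TRUE)

  M4 <- matrix(0, 4, 4)
  M4[upper.tri(M4)] <- 1:6
  M4 <- M4 + t(M4)
  X4 <- ipf_normalise(M4)
  expect_lt(max(abs(rowSums(X4) - 1)), 1e-8)
  expect_lt(max(abs(colSums(X4) - 1)), 1e-8)
  expect_equal(unclass(X4), oracle_ipf(M4), ignore_attr = TRUE, tolerance = 1e-8)
})

test_that("IPF is scale invariant, symmetric, zero-diagonal", {
  set.seed(13)
  M <- random_weighted_graph(6, p = 0.8)
  X <- ipf_normalise(M)
  Xc <- ipf_normalise(37.5 * M)
  expect_equal(unclass(X), unclass(Xc), ignore_attr = TRUE, tolerance = 1e-8)
  expect_equal(unclass(X), t(unclass(X)), ignore_attr = TRUE)
  expect_equal(diag(X), rep(0, 6))
})

test_that("IPF reports non-convergence on infeasible supports", {
  # path 1-2-3: no doubly stochastic matrix lives on this support
  P <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_error(ipf_normalise(P, max_iter = 200), "did not converge")
  expect_error(ipf_normalise(matrix(c(0, -1, -1, 0), 2, 2)), "non-negative")
  expect_error(ipf_normalise(matrix(c(1, 1, 1, 0), 2, 2)), "zero diagonal")
  expect_error(ipf_normalise(matrix(c(0, 1, 0, 1, 0, 0, 0, 0, 0), 3, 3)),
               "positive entry")
})

test_that("compute_all_weights composes the single-pair measures", {
  x <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 1), c(0, 1, 0), c(0, 0, 1),
             c(1, 1, 0), c(0, 1, 1), c(1, 0, 0))
  counts <- tabulate_cooccurrence(binary_cohort(x))
  w <- compute_all_weights(counts)
  expect_equal(nrow(w), 3L)
  for (k in seq_len(3)) {
    i <- w$i[k]; j <- w$j[k]
    n11 <- sum(x[, i] & x[, j])
    t <- pair_table(n11, sum(x[, i]) - n11, sum(x[, j]) - n11,
                    sum(!x[, i] & !x[, j]))
    expect_equal(w$or[k], odds_ratio(t))
    expect_equal(w$lift[k], lift(t))
    expect_equal(w$phi[k], phi_coefficient(t))
    expect_equal(w$sci[k], salton_cosine(t))
  }
  # NF column comes from IPF of the joint matrix
  nf <- ipf_normalise(counts$joint)
  expect_equal(w$nf, nf[cbind(w$i, w$j)])
})

test_that("independence-structured cohorts give OR = lift = 1, phi = 0", {
  co <- generate_cohort(40000, prevalence = c(40, 30, 20, 10), seed = 17)
  w <- compute_all_weights(co)
  expect_true(all(abs(w$or - 1) < 0.15))
  expect_true(all(abs(w$lift - 1) < 0.1))
  expect_true(all(abs(w$phi) < 0.02))
})

test_that("all five weights are symmetric in the two conditions", {
  t <- pair_table(12, 5, 9, 30)
  ts <- pair_table(12, 9, 5, 30)  # swap the conditions
  expect_equal(odds_ratio(t), odds_ratio(ts))
  expect_equal(lift(t), lift(ts))
  expect_equal(phi_coefficient(t), phi_coefficient(ts))
  expect_equal(salton_cosine(t), salton_cosine(ts))
})
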
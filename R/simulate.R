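#' Planted block association structure
#'
#' Describes the latent dependence used by [generate_cohort()]: conditions
#' in the same block share latent correlation `rho_within`, conditions in
#' different blocks `rho_between`, and conditions listed in `isolated` have
#' latent correlation 0 with every other condition regardless of block.
#'
#' @param blocks vector of block labels, one per condition (names or
#'   positions give the condition ids).
#' @param rho_within latent correlation for same-block pairs, in (-1, 1).
#' @param rho_between latent correlation for cross-block pairs; must not
#'   exceed `rho_within`.
#' @param isolated integer/character ids of conditions forced independent
#'   of all others.
#' @return an object of class `planted_structure`.
#' @export
planted_structure <- function(blocks, rho_within = 0.5, rho_between = 0,
                              isolated = integer()) {
  if (!(rho_between > -1 && rho_between <= rho_within && rho_within < 1))
    stop("need -1 < rho_between <= rho_within < 1")
  structure(list(blocks = blocks, rho_within = rho_within,
                 rho_between = rho_between, isolated = isolated),
            class = "planted_structure")
}

#' Latent correlation matrix implied by a planted structure
#'
#' Unit diagonal; off-diagonal entries are `rho_within` for same-block
#' pairs, `rho_between` for cross-block pairs, and 0 for any pair touching
#' an isolated condition. If the resulting matrix is not positive
#' semi-definite it is repaired by clipping negative eigenvalues at zero
#' and renormalising to unit diagonal.
#'
#' @param structure a [planted_structure()].
#' @param D number of conditions (defaults to `length(structure$blocks)`).
#' @return a D x D PSD correlation matrix.
#' @export
planted_correlation_matrix <- function(structure, D = length(structure$blocks)) {
  b <- structure$blocks
  if (length(b) != D) stop("every condition must be assigned a block")
  R <- matrix(structure$rho_between, D, D)
  same <- outer(b, b, "==")
  R[same] <- structure$rho_within
  iso <- structure$isolated
  if (is.character(iso)) iso <- match(iso, names(b))
  if (length(iso)) {
    R[iso, ] <- 0
    R[, iso] <- 0
  }
  diag(R) <- 1
  repair_psd(R)
}

# Eigenvalue clipping at 0, then renormalisation to unit diagonal.
# Tolerance 1e-8 on the most negative admissible eigenvalue.
repair_psd <- function(R, tol = 1e-8) {
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) >= -tol * max(abs(e$values))) {
    if (min(e$values) >= 0) return(R)
  }
  v <- pmax(e$values, 0)
  R2 <- e$vectors %*% (v * t(e$vectors))
  d <- sqrt(diag(R2))
  if (any(d <= 0)) stop("correlation matrix not repairable to PSD")
  R2 <- R2 / outer(d, d)
  diag(R2) <- 1
  (R2 + t(R2)) / 2
}

#' Generate a synthetic binary cohort
#'
#' Draws condition indicators from a Gaussian copula: a latent multivariate
#' normal vector with the planted block correlation matrix is thresholded
#' coordinate-wise so that condition `d` has marginal prevalence
#' `prevalence[d]` percent (indicator 1 when the latent coordinate exceeds
#' the `1 - prevalence[d]/100` standard-normal quantile). The copula gives
#' exact marginal control with tunable pairwise dependence, which is all
#' the downstream association analysis sees.
#'
#' With `require_multimorbidity = TRUE` (mirroring cohorts restricted to
#' subjects with two or more conditions), subjects with fewer than 2
#' positive indicators are redrawn by rejection sampling, so `n_subjects`
#' is exact and the retained marginals are the conditional ones.
#'
#' @param n_subjects number of subjects to generate.
#' @param prevalence per-condition target prevalences in percent, each in
#'   (0, 100). Defaults to the bundled reference prevalences
#'   ([reference_conditions()]).
#' @param structure a [planted_structure()]; default: all conditions in
#'   one block with `rho_within = 0`, i.e. independence.
#' @param seed integer seed; the single source of randomness for the draw
#'   (redraws consume the same stream).
#' @param require_multimorbidity redraw subjects with < 2 conditions?
#' @param labels condition labels; defaults to names of `prevalence`,
#'   or the reference labels when `prevalence` is left at its default.
#' @return a [binary_cohort()].
#' @examples
#' g <- generate_cohort(500, prevalence = c(A = 30, B = 20, C = 10), seed = 1)
#' colMeans(g)
#' @export
generate_cohort <- function(n_subjects, prevalence = NULL, structure = NULL,
                            seed = 1L, require_multimorbidity = FALSE,
                            labels = NULL) {
  if (n_subjects < 1L) stop("n_subjects must be >= 1")
  if (is.null(prevalence)) {
    ref <- reference_conditions()
    prevalence <- ref$prevalence
    if (is.null(labels)) labels <- ref$label
  }
  if (any(prevalence <= 0 | prevalence >= 100))
    stop("prevalences must lie strictly between 0 and 100 (percent)")
  D <- length(prevalence)
  if (is.null(labels)) labels <- names(prevalence)
  if (is.null(labels)) labels <- paste0("C", seq_len(D))
  if (is.null(structure)) structure <- planted_structure(rep(1L, D), rho_within = 0)
  R <- planted_correlation_matrix(structure, D)
  thresh <- qnorm(1 - prevalence / 100)

  set.seed(seed)
  draw <- function(n) {
    z <- MASS::mvrnorm(n, mu = rep(0, D), Sigma = R)
    if (n == 1L) z <- matrix(z, nrow = 1L)
    matrix(as.integer(t(z) > thresh), ncol = D, byrow = TRUE)
  }
  x <- draw(n_subjects)
  if (require_multimorbidity) {
    total_drawn <- n_subjects
    repeat {
      bad <- which(rowSums(x) < 2L)
      if (!length(bad)) break
      total_drawn <- total_drawn + length(bad)
      if (total_drawn > 100 * n_subjects)
        stop("rejection rate above 99%: prevalences too low for a multimorbid cohort")
      x[bad, ] <- draw(length(bad))
    }
  }
  colnames(x) <- labels
  binary_cohort(x)
}
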
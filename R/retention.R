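#' Principal-components eigenvalue spectrum of a correlation matrix
#'
#' Descending eigenvalues of the full (not reduced) correlation matrix; each
#' eigenvalue is the variance explained by the corresponding principal
#' component, and the spectrum sums to J.
#'
#' @param R symmetric correlation matrix (or `correlation_estimate`).
#' @return numeric vector of length J, non-increasing.
#' @export
eigen_spectrum <- function(R) {
  M <- unclass_matrix(R)
  if (max(abs(M - t(M))) > 1e-8) stop("input matrix is not symmetric")
  eigen(M, symmetric = TRUE, only.values = TRUE)$values
}

#' Kaiser eigenvalue-greater-than-one rule
#'
#' Number of eigenvalues strictly greater than 1; a component should explain
#' at least as much variance as a single standardized item.
#'
#' @param spectrum descending eigenvalues from [eigen_spectrum()].
#' @return integer count.
#' @export
kaiser_count <- function(spectrum) {
  sum(spectrum > 1)
}

#' Acceleration-factor scree rule
#'
#' Locates the scree elbow as the point where the slope of the eigenvalue
#' plot changes most abruptly: the acceleration at position i is the second
#' difference `e[i+1] - 2 e[i] + e[i-1]` (defined for i = 2..J-1), and the
#' retained count is the position preceding its maximum. Ties go to the first
#' index attaining the maximum, so the result lies in `[1, J-2]`.
#'
#' @param spectrum descending eigenvalues, length at least 3.
#' @return integer retained-factor count.
#' @export
acceleration_factor <- function(spectrum) {
  J <- length(spectrum)
  if (J < 3L) stop("acceleration factor needs at least 3 eigenvalues")
  i <- 2:(J - 1L)
  af <- spectrum[i + 1L] - 2 * spectrum[i] + spectrum[i - 1L]
  i[which.max(af)] - 1L
}

#' Combine a retention count with the Kaiser bound
#'
#' The acceleration factor (and revised parallel analysis) are often paired
#' with the Kaiser rule by taking the minimum of the two counts, so that no
#' retained factor has an eigenvalue below 1.
#'
#' @param m_a count from the other rule.
#' @param m_kaiser Kaiser count.
#' @return `min(m_a, m_kaiser)`.
#' @export
combine_with_kaiser <- function(m_a, m_kaiser) {
  stopifnot(m_a >= 0, m_kaiser >= 0)
  min(m_a, m_kaiser)
}

#' Traditional parallel analysis
#'
#' Compares the observed principal-components eigenvalues with those of `k`
#' datasets of independent standard normals with the same N and J. Comparison
#' datasets are pushed through the same arm pipeline as the observed data
#' (dichotomized at the arm's threshold, correlated with the arm's method), so
#' the null reference matches the observed estimator. The retained count is
#' the largest m such that every observed eigenvalue up to m strictly exceeds
#' its reference (mean or 95th percentile across the k draws), stopping at the
#' first failure.
#'
#' @param sample observed data matrix, already in the arm's representation
#'   (continuous, or 0/1 for dichotomized arms).
#' @param arm one element of [analysis_arms()].
#' @param reference `"mean"` or `"p95"`.
#' @param k number of comparison datasets.
#' @param obs_corr optional precomputed observed arm correlation matrix.
#' @return integer retained-factor count in `[0, J]`.
#' @export
parallel_analysis <- function(sample, arm, reference = c("p95", "mean"),
                              k = 100L, obs_corr = NULL) {
  reference <- match.arg(reference)
  if (k < 2L) stop("k must be at least 2")
  N <- nrow(sample); J <- ncol(sample)
  if (is.null(obs_corr)) obs_corr <- arm_correlation(sample, arm)
  obs <- eigen_spectrum(obs_corr)
  sims <- .null_reference_eigs(N, J, arm, k)
  ref <- if (reference == "mean") colMeans(sims)
         else apply(sims, 2L, stats::quantile, probs = 0.95, names = FALSE)
  .sequential_count(obs, ref)
}

# eigenvalue draws of arm-processed pure-noise datasets (k x J)
.null_reference_eigs <- function(N, J, arm, k) {
  sims <- matrix(NA_real_, k, J)
  for (i in seq_len(k)) {
    for (try in 1:100) {
      X <- matrix(stats::rnorm(N * J), N, J)
      D <- arm_transform(X, arm)
      if (.arm_data_ok(D, arm)) break
      if (try == 100) stop("could not draw a non-degenerate comparison dataset")
    }
    sims[i, ] <- eigen_spectrum(arm_correlation(D, arm))
  }
  sims
}

.sequential_count <- function(obs, ref) {
  m <- 0L
  for (i in seq_along(obs)) {
    if (obs[i] > ref[i]) m <- i else break
  }
  m
}

#' Revised parallel analysis
#'
#' Sequential variant of parallel analysis in which the reference distribution
#' for the (m+1)th eigenvalue comes from data simulated under an m-factor
#' model rather than from pure noise. At stage m an m-factor model is fit to
#' the observed arm correlation matrix (see [implied_correlation()]; stage 0
#' uses the identity); `k` comparison datasets of size N are generated from
#' the implied correlation matrix, pushed through the arm pipeline, and
#' factor m+1 is retained iff the observed (m+1)th principal-components
#' eigenvalue exceeds the 95th percentile of its simulated counterparts (and
#' also exceeds 1 when `with_kaiser`). The procedure stops at the first
#' failure.
#'
#' @inheritParams parallel_analysis
#' @param with_kaiser also require eigenvalues greater than 1 (equivalently,
#'   the minimum of the plain revised-parallel-analysis count and the Kaiser
#'   count).
#' @param model how the m-factor generating model is fit to the observed
#'   correlation matrix. `"efa"` (default) uses an unweighted least-squares
#'   common-factor fit (iterated principal axes), whose residual uniquenesses
#'   keep the null reference calibrated: when the m-factor model is adequate,
#'   the observed (m+1)th eigenvalue is an ordinary draw from the comparison
#'   distribution. `"pca"` takes the first m principal-component loadings
#'   instead; because components absorb unique variance, the implied residual
#'   spectrum is compressed and the test loses its calibration, retained only
#'   for comparison.
#' @return integer retained-factor count.
#' @export
revised_parallel_analysis <- function(sample, arm, k = 100L,
                                      with_kaiser = FALSE, obs_corr = NULL,
                                      model = c("efa", "pca")) {
  model <- match.arg(model)
  if (k < 2L) stop("k must be at least 2")
  N <- nrow(sample); J <- ncol(sample)
  if (is.null(obs_corr)) obs_corr <- arm_correlation(sample, arm)
  obs <- eigen_spectrum(obs_corr)
  Mobs <- unclass_matrix(obs_corr)
  m <- 0L
  implied <- diag(J)
  repeat {
    e_next <- vapply(seq_len(k), function(i) {
      for (try in 1:100) {
        Z <- draw_continuous_sample(implied, N)
        D <- arm_transform(Z, arm)
        if (.arm_data_ok(D, arm))
          return(eigen_spectrum(arm_correlation(D, arm))[m + 1L])
      }
      stop("could not draw a non-degenerate comparison dataset")
    }, numeric(1))
    thr <- stats::quantile(e_next, probs = 0.95, names = FALSE)
    ok <- obs[m + 1L] > thr && (!with_kaiser || obs[m + 1L] > 1)
    if (!ok) return(m)
    m <- m + 1L
    if (m > J - 2L) return(m)
    implied <- implied_correlation(Mobs, m, model = model)
  }
}

#' Implied correlation matrix of an m-factor approximation
#'
#' Fits an m-factor model to a correlation matrix and returns the implied
#' correlation matrix `Lambda_m Lambda_m'` with the diagonal reset to 1
#' (smoothed to positive definite if necessary). The `"efa"` method is an
#' unweighted least-squares common-factor fit by iterated principal axes:
#' starting from squared-multiple-correlation communalities, the reduced
#' matrix is re-decomposed until the communalities stabilize (Heywood cases
#' are capped at 0.995). The `"pca"` method uses the first m
#' principal-component loadings `U_m D_m^(1/2)` directly.
#'
#' @param R correlation matrix.
#' @param m number of factors (0 returns the identity).
#' @param model `"efa"` or `"pca"`.
#' @return a plain J x J positive-definite correlation matrix.
#' @export
implied_correlation <- function(R, m, model = c("efa", "pca")) {
  model <- match.arg(model)
  M <- unclass_matrix(R)
  J <- ncol(M)
  if (m == 0L) return(diag(J))
  if (model == "pca") {
    eg <- eigen(M, symmetric = TRUE)
    Lm <- eg$vectors[, seq_len(m), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(m)], 0)), m)
  } else {
    Lm <- .paf_loadings(M, m)
  }
  implied <- tcrossprod(Lm)
  diag(implied) <- 1
  unclass_matrix(repair_psd(new_correlation_estimate(
    implied, kind = "pearson", n_obs = NA_integer_)))
}

# iterated principal-axis factoring (unweighted least squares flavor):
# communalities start at squared multiple correlations and are re-estimated
# from the top-m eigenpairs of the reduced matrix until stable
.paf_loadings <- function(M, m, maxit = 100L, tol = 1e-5) {
  J <- ncol(M)
  Minv <- tryCatch(solve(M), error = function(e) NULL)
  h2 <- if (is.null(Minv)) rep(0.5, J) else pmin(pmax(1 - 1 / diag(Minv), 0.05), 0.995)
  for (it in seq_len(maxit)) {
    Mr <- M
    diag(Mr) <- h2
    eg <- eigen(Mr, symmetric = TRUE)
    d <- pmax(eg$values[seq_len(m)], 0)
    Lm <- eg$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
    h2_new <- pmin(rowSums(Lm^2), 0.995)
    if (max(abs(h2_new - h2)) < tol) {
      h2 <- h2_new
      break
    }
    h2 <- h2_new
  }
  Mr <- M
  diag(Mr) <- h2
  eg <- eigen(Mr, symmetric = TRUE)
  d <- pmax(eg$values[seq_len(m)], 0)
  eg$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(d), m)
}

#' Velicer's average squared partial correlation
#'
#' After partialing out the first m principal components, `map_statistic`
#' returns the mean squared off-diagonal partial correlation
#' `f_m = sum_{v != w} (a*_vw)^2 / (J (J - 1))`; `m = 0` gives the mean
#' squared off-diagonal of `R` itself.
#'
#' @param R correlation matrix.
#' @param m number of components partialed out, `0 <= m <= J - 2`.
#' @return scalar in `[0, 1]`.
#' @export
map_statistic <- function(R, m) {
  M <- unclass_matrix(R)
  J <- ncol(M)
  if (m < 0 || m > J - 2L) stop("m must lie in [0, J-2]")
  off <- upper.tri(M)
  if (m == 0L) return(2 * sum(M[off]^2) / (J * (J - 1)))
  eg <- eigen(M, symmetric = TRUE)
  Lm <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(m)], 0)), m)
  A <- M - tcrossprod(Lm)
  d <- diag(A)
  if (any(d <= 1e-10))
    stop(sprintf("partialing out %d component(s) leaves a degenerate diagonal", m))
  P <- A / sqrt(tcrossprod(d))
  2 * sum(P[off]^2) / (J * (J - 1))
}

#' Minimum-average-partial retained-component count
#'
#' Evaluates the average squared partial correlation `f_m` over
#' m = 0, 1, ..., J-2 and returns the position of its global minimum; no
#' components are extracted (0) when `f_0` itself is smallest, which covers
#' the textbook `f_1 > f_0` stopping case with a monotone sequence. Ties go
#' to the smaller m. A degenerate partialing diagonal truncates the candidate
#' range at the last valid m.
#'
#' @param R correlation matrix.
#' @return integer in `[0, J - 2]`.
#' @export
map_count <- function(R) {
  M <- unclass_matrix(R)
  J <- ncol(M)
  f <- rep(NA_real_, J - 1L)
  for (m in 0:(J - 2L)) {
    fm <- tryCatch(map_statistic(M, m), error = function(e) NULL)
    if (is.null(fm)) break
    f[m + 1L] <- fm
  }
  f <- f[!is.na(f)]
  which.min(f) - 1L
}
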
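#' Draw a multivariate-normal sample from a population correlation matrix
#'
#' Uses the eigendecomposition route: with `R = U D U'`, set `F = U D^(1/2)`
#' and return `Z = X F'` where `X` is an N x J matrix of independent standard
#' normals. Eigenvalues are clipped at zero before the square root to absorb
#' negative round-off. Rows of `Z` are exactly multivariate normal with
#' correlation `R` and unit variances.
#'
#' @param model a `population_model`, or any J x J positive semi-definite
#'   correlation matrix.
#' @param n_obs sample size N (at least 3).
#' @return an N x J numeric matrix.
#' @export
draw_continuous_sample <- function(model, n_obs) {
  R <- if (inherits(model, "population_model")) model$R else as.matrix(model)
  if (!all(is.finite(R))) stop("population correlation matrix has non-finite entries")
  n_obs <- as.integer(n_obs)
  if (n_obs < 3L) stop("n_obs must be at least 3")
  Fm <- .sampling_factor(R)
  J <- ncol(R)
  X <- matrix(stats::rnorm(n_obs * J), n_obs, J)
  X %*% t(Fm)
}

# F = U D^(1/2) with eigenvalues clipped at 0; F F' = R up to round-off
.sampling_factor <- function(R) {
  eg <- eigen(R, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  eg$vectors %*% diag(sqrt(d), length(d))
}

#' Dichotomize a continuous sample at a threshold
#'
#' Entries strictly greater than `delta` become 1, all others (including exact
#' ties, a probability-zero event under the normal model) become 0. With
#' standard-normal margins, `delta = 0` yields a 50-50 split of zeroes and
#' ones and `delta = qnorm(0.75)` (about 0.674) a 75-25 split.
#'
#' @param sample numeric matrix of continuous values.
#' @param delta finite scalar cut-off.
#' @return integer 0/1 matrix of the same dimensions.
#' @export
dichotomize <- function(sample, delta) {
  if (!is.finite(delta)) stop("delta must be finite")
  out <- (sample > delta) + 0L
  storage.mode(out) <- "integer"
  out
}
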
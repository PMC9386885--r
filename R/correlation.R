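#' Pearson correlation matrix with provenance
#'
#' Product-moment correlations of the columns of `X`, wrapped as a
#' `correlation_estimate` (symmetric, unit diagonal, tagged with its kind and
#' sample size). Constant columns are an error because the correlation is
#' undefined there.
#'
#' @param X numeric N x J matrix (continuous or 0/1).
#' @return a `correlation_estimate`.
#' @export
pearson_matrix <- function(X) {
  X <- as.matrix(X)
  v <- apply(X, 2L, stats::var)
  if (any(v == 0))
    stop(sprintf("degenerate column(s) with zero variance: %s",
                 paste(which(v == 0), collapse = ", ")))
  R <- stats::cor(X)
  new_correlation_estimate(R, kind = "pearson", n_obs = nrow(X))
}

#' Tetrachoric correlation of a 2x2 table
#'
#' Maximum-likelihood estimate of the latent bivariate-normal correlation
#' underlying a 2x2 table of dichotomized outcomes. Thresholds are fixed at
#' the standard-normal quantiles of the observed margins; the correlation
#' maximizes the multinomial likelihood of the table over (-0.999, 0.999) by
#' one-dimensional search. Any empty cell triggers a +0.5 continuity
#' correction to all four cells so the estimate stays finite.
#'
#' @param n00,n01,n10,n11 non-negative cell counts; `nab` counts observations
#'   with first variable `a` and second variable `b`.
#' @return scalar estimate in (-1, 1).
#' @export
tetrachoric_pair <- function(n00, n01, n10, n11) {
  counts <- c(n00, n01, n10, n11)
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (sum(counts) < 4) stop("total count must be at least 4")
  if (n00 + n01 == 0 || n10 + n11 == 0 || n00 + n10 == 0 || n01 + n11 == 0)
    stop("degenerate margin: one variable is constant")
  .tetrachoric_pairs_cpp(n00, n01, n10, n11)[1L]
}

#' Tetrachoric correlation matrix of a binary data matrix
#'
#' Pairwise maximum-likelihood tetrachoric correlations over all column pairs.
#' Because pairwise estimates need not form a positive semi-definite matrix,
#' an indefinite result is passed through [repair_psd()] and flagged.
#'
#' @param B N x J matrix with entries in 0/1.
#' @return a `correlation_estimate` of kind `"tetrachoric"`; the `repaired`
#'   attribute records whether smoothing was applied.
#' @export
tetrachoric_matrix <- function(B) {
  B <- as.matrix(B)
  N <- nrow(B); J <- ncol(B)
  ones <- colSums(B)
  if (any(ones == 0L | ones == N))
    stop(sprintf("degenerate margin in column(s): %s",
                 paste(which(ones == 0L | ones == N), collapse = ", ")))
  C11 <- crossprod(B)
  pairs <- which(upper.tri(C11), arr.ind = TRUE)
  n11 <- C11[pairs]
  n10 <- ones[pairs[, 1L]] - n11
  n01 <- ones[pairs[, 2L]] - n11
  n00 <- N - n11 - n10 - n01
  rho <- .tetrachoric_pairs_cpp(n00, n01, n10, n11)
  R <- diag(J)
  R[pairs] <- rho
  R[pairs[, c(2L, 1L), drop = FALSE]] <- rho
  est <- new_correlation_estimate(R, kind = "tetrachoric", n_obs = N)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) est <- repair_psd(est)
  est
}

#' Repair an indefinite correlation matrix
#'
#' Eigenvalue clipping: eigenvalues below `1e-6` are raised to `1e-6`, the
#' matrix is reassembled and rescaled to unit diagonal (repeated until the
#' rescaling no longer pushes an eigenvalue back under the floor).
#' Positive-definite inputs are returned unchanged with `repaired = FALSE`;
#' the largest entry change is recorded in the `max_change` attribute.
#'
#' @param R symmetric matrix with unit diagonal, or a `correlation_estimate`.
#' @return a `correlation_estimate` with `repaired` set accordingly.
#' @export
repair_psd <- function(R) {
  kind <- attr(R, "kind") %||% "pearson"
  n_obs <- attr(R, "n_obs") %||% NA_integer_
  M <- unclass_matrix(R)
  eg <- eigen(M, symmetric = TRUE)
  if (min(eg$values) >= 1e-6) {
    out <- new_correlation_estimate(M, kind = kind, n_obs = n_obs)
    attr(out, "repaired") <- isTRUE(attr(R, "repaired"))
    attr(out, "max_change") <- attr(R, "max_change") %||% 0
    return(out)
  }
  # clip-and-rescale can push an eigenvalue back under the floor; iterate
  M2 <- M
  for (it in 1:50) {
    eg2 <- eigen(M2, symmetric = TRUE)
    if (min(eg2$values) >= 1e-6 * (1 - 1e-6)) break
    d <- pmax(eg2$values, 1e-6)
    M2 <- eg2$vectors %*% diag(d, length(d)) %*% t(eg2$vectors)
    s <- 1 / sqrt(diag(M2))
    M2 <- M2 * tcrossprod(s)
    diag(M2) <- 1
    M2 <- (M2 + t(M2)) / 2
  }
  out <- new_correlation_estimate(M2, kind = kind, n_obs = n_obs)
  attr(out, "repaired") <- TRUE
  attr(out, "max_change") <- max(abs(M2 - M))
  out
}

#' Construct a correlation-estimate object
#'
#' @param R symmetric J x J matrix, unit diagonal, entries in `[-1, 1]`.
#' @param kind `"pearson"` or `"tetrachoric"`.
#' @param n_obs sample size behind the estimate.
#' @return matrix of class `correlation_estimate` with `kind`, `n_obs`,
#'   `repaired` attributes.
#' @export
new_correlation_estimate <- function(R, kind, n_obs) {
  R <- as.matrix(R)
  if (max(abs(R - t(R))) > 1e-12) stop("correlation matrix not symmetric")
  R <- (R + t(R)) / 2
  if (max(abs(diag(R) - 1)) > 1e-8) stop("correlation matrix diagonal must be 1")
  diag(R) <- 1
  if (max(abs(R)) > 1 + 1e-8) stop("correlation entries must lie in [-1, 1]")
  R[R > 1] <- 1; R[R < -1] <- -1
  structure(R, kind = match.arg(kind, c("pearson", "tetrachoric")),
            n_obs = n_obs, repaired = FALSE,
            class = c("correlation_estimate", "matrix", "array"))
}

# strip estimator attributes, keep the plain matrix
unclass_matrix <- function(R) {
  M <- as.matrix(R)
  attributes(M) <- list(dim = dim(M))
  M
}

`%||%` <- function(a, b) if (is.null(a)) b else a
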
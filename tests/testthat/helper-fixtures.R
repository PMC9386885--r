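# shared fixtures: built in code, deterministic

study_spec <- function(communality = c("low", "high"), theta = 0, seed = 101L) {
  communality <- match.arg(communality)
  levels <- if (communality == "low") c(0.2, 0.3, 0.4) else c(0.6, 0.7, 0.8)
  population_spec(n_items = 20L, n_major = 3L, n_minor = 200L,
                  communality_levels = levels, interfactor_corr = theta,
                  common_ratio = 0.8, seed = seed)
}

# clean 3-block population: loadings 0.8, 7/7/6 items, no minor factors
block_population <- function(loading = 0.8, theta = 0) {
  spec <- population_spec(n_items = 20L, n_major = 3L, n_minor = 0L,
                          communality_levels = loading^2,
                          interfactor_corr = theta, seed = 1L)
  assemble_population(spec)
}

unclass_matrix_plain <- function(R) {
  M <- as.matrix(R)
  attributes(M) <- list(dim = dim(M))
  M
}

unclass_matrix_sym_dev <- function(R) {
  M <- unclass_matrix_plain(R)
  max(abs(M - t(M)))
}

# small random correlation matrix (always PD)
random_corr <- function(J, seed) {
  set.seed(seed)
  X <- matrix(rnorm(5 * J * J), 5 * J, J)
  cor(X)
}

# brute-force average squared partial correlation, explicit loops
map_statistic_bruteforce <- function(R, m) {
  R <- as.matrix(R)
  J <- ncol(R)
  if (m == 0) {
    acc <- 0
    for (v in seq_len(J)) for (w in seq_len(J)) if (v != w)
      acc <- acc + R[v, w]^2 / (J * (J - 1))
    return(acc)
  }
  eg <- eigen(R, symmetric = TRUE)
  L <- eg$vectors[, seq_len(m), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(m)]), m)
  A <- R - L %*% t(L)
  acc <- 0
  for (v in seq_len(J)) for (w in seq_len(J)) if (v != w)
    acc <- acc + (A[v, w] / sqrt(A[v, v] * A[w, w]))^2 / (J * (J - 1))
  acc
}

# direct evaluation of the merge-cost of joining communities C1 and C2:
# (1/n) * (sum of squared node-to-community distances in the merged community
#          minus the sums within C1 and C2), with community profiles the plain
# average of member walk profiles and the metric weighted by 1/strength
dsigma_direct <- function(A, members1, members2, steps = 4L, lazy = TRUE) {
  n <- ncol(A)
  act <- which(rowSums(A) > 0)
  Aw <- A[act, act, drop = FALSE]
  if (lazy) Aw <- Aw + diag(rowSums(Aw))
  wk <- rowSums(Aw)
  P <- Aw / wk
  Pt <- P
  if (steps > 1) for (s in seq_len(steps - 1)) Pt <- Pt %*% P
  prof <- function(members) colMeans(Pt[match(members, act), , drop = FALSE])
  ssd <- function(members) {
    pc <- prof(members)
    sum(vapply(members, function(v)
      sum((Pt[match(v, act), ] - pc)^2 / wk), numeric(1)))
  }
  (ssd(c(members1, members2)) - ssd(members1) - ssd(members2)) / n
}

# modularity by exhaustive enumeration over the partitions of a merge trace
best_modularity_exhaustive <- function(A, levels) {
  max(vapply(levels, function(asg) graph_modularity(A, asg), numeric(1)))
}
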
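#' EBIC-tuned Gaussian graphical model (graphical lasso)
#'
#' Estimates a sparse inverse-covariance (precision) matrix by the graphical
#' lasso over a log-spaced penalty grid from `lambda_max` (the largest
#' off-diagonal absolute correlation, the smallest penalty that empties the
#' graph) down to `lambda_max * lambda_min_ratio`, selecting the penalty that
#' minimizes the extended Bayesian information criterion
#' `EBIC = -2 L + E log n + 4 gamma E log J`, where
#' `L = (n/2) (log det K - tr(S K))` and `E` counts nonzero upper-triangle
#' off-diagonal precision entries. Edge weights of the returned network are
#' absolute partial correlations `-K_vw / sqrt(K_vv K_ww)`.
#'
#' @param S correlation matrix (smoothed to positive definite if needed).
#' @param n sample size behind `S`.
#' @param gamma EBIC hyperparameter (0 recovers plain BIC; 0.5 is the common
#'   default for sparse graphs).
#' @param n_lambda number of penalty values on the grid.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @return an object of class `ggm_network`: list with `weights` (J x J
#'   non-negative, zero diagonal), `partial_corr` (signed), `precision`,
#'   `strength` (row sums of `weights`), `lambda`, `ebic`, `n_obs`.
#' @export
ebic_glasso <- function(S, n, gamma = 0.5, n_lambda = 100L,
                        lambda_min_ratio = 0.01) {
  kind <- attr(S, "kind") %||% "pearson"
  M <- unclass_matrix(S)
  J <- ncol(M)
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-6)
    M <- unclass_matrix(repair_psd(new_correlation_estimate(M, kind = kind,
                                                            n_obs = n)))
  lmax <- max(abs(M[upper.tri(M)]))
  if (lmax < 1e-10) {
    # no marginal association at all: empty network at every penalty
    K <- diag(J)
  } else {
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = n_lambda))
    path <- .glasso_path_cpp(M, lambdas)$precision
    ebic <- vapply(seq_len(n_lambda), function(i) {
      K <- path[, , i]
      ld <- determinant(K, logarithm = TRUE)
      if (ld$sign <= 0) return(Inf)
      L <- (n / 2) * (as.numeric(ld$modulus) - sum(M * K))
      E <- sum(abs(K[upper.tri(K)]) > 1e-8)
      -2 * L + E * log(n) + 4 * gamma * E * log(J)
    }, numeric(1))
    if (all(!is.finite(ebic))) stop("no positive-definite solution on the penalty grid")
    best <- which.min(ebic)
    K <- path[, , best]
  }
  pc <- -K / sqrt(tcrossprod(diag(K)))
  diag(pc) <- 0
  pc[abs(pc) < 1e-8] <- 0
  w <- abs(pc)
  net <- list(weights = w, partial_corr = pc, precision = K,
              strength = rowSums(w), n_obs = n)
  if (lmax >= 1e-10) {
    net$lambda <- lambdas[best]
    net$ebic <- ebic[best]
  }
  structure(net, class = "ggm_network")
}

#' Walktrap community detection on a weighted network
#'
#' Agglomerative community detection driven by short random walks. With edge
#' weights `a_vw` and node strengths `NS_v = sum_w a_vw`, the walk is made
#' lazy by a self-loop of weight `NS_v` on every node (so `p_vv = 1/2`, the
#' reference implementation's convention, which keeps the chain aperiodic);
#' raising the transition matrix to `steps` gives each node a walk profile.
#' The squared distance between nodes (or communities, whose profile is the
#' plain average of their members') is `sum_k (p_vk - p_wk)^2 / NS'_k` with
#' `NS'` the lazy strengths. Starting from singletons, the pair of *adjacent*
#' communities whose merge least increases the within-community variation
#' `Delta sigma(C1, C2) = (1/n) * |C1||C2|/(|C1|+|C2|) * d^2(C1, C2)`
#' is merged at each step (the Ward form of the direct sum-of-squared-distance
#' difference); merging stops when no two remaining communities share an edge,
#' so disconnected components are never merged. Zero-strength nodes take no
#' part in the walk and remain singleton communities.
#'
#' @param net a `ggm_network`, or a symmetric non-negative weight matrix with
#'   zero diagonal.
#' @param steps random-walk length (the Walktrap convention is 4; 1 gives the
#'   plain transition profile).
#' @param lazy add the aperiodicity self-loops (`TRUE`, the reference
#'   convention); `FALSE` walks on the bare weights.
#' @return an object of class `walktrap_partition`: list with `assignment`
#'   (modularity-maximizing labels), `n_communities` (communities containing
#'   at least one connected node; isolated nodes keep singleton labels but are
#'   excluded from the count, mirroring how network psychometrics treats
#'   disconnected items), `n_isolated`, `modularity`, `merge_trace` (data
#'   frame of merges with their `dsigma`), and `levels` (list of assignment
#'   vectors, one per agglomeration level, with their modularity in
#'   `level_modularity`).
#' @export
walktrap_partition <- function(net, steps = 4L, lazy = TRUE) {
  A <- if (inherits(net, "ggm_network")) net$weights else as.matrix(net)
  J <- ncol(A)
  if (any(A < 0) || max(abs(diag(A))) > 0)
    stop("weights must be non-negative with zero diagonal")
  NS <- rowSums(A)
  active <- which(NS > 0)
  if (!length(active)) {
    assignment <- seq_len(J)
    return(structure(list(assignment = assignment, n_communities = 0L,
                          n_isolated = J, modularity = NA_real_,
                          merge_trace = data.frame(step = integer(), c1 = integer(),
                                                   c2 = integer(), dsigma = numeric()),
                          levels = list(assignment),
                          level_modularity = NA_real_),
                     class = "walktrap_partition"))
  }
  Aw <- A[active, active, drop = FALSE]
  if (lazy) Aw <- Aw + diag(rowSums(Aw))
  wk <- rowSums(Aw)  # metric weights 1/NS_k over walk-reachable nodes
  P <- Aw / wk
  Pt <- P
  if (steps > 1L) for (s in seq_len(steps - 1L)) Pt <- Pt %*% P

  # community state over active nodes
  comm <- as.list(seq_along(active))          # member indices (into active)
  profiles <- lapply(seq_along(active), function(i) Pt[i, ])
  Aact <- A[active, active, drop = FALSE]

  assignment_from <- function(comm) {
    asg <- integer(J)
    for (ci in seq_along(comm)) asg[active[comm[[ci]]]] <- ci
    iso <- setdiff(seq_len(J), active)
    asg[iso] <- length(comm) + seq_along(iso)
    asg
  }

  levels <- list(assignment_from(comm))
  trace <- list()
  step <- 0L
  while (length(comm) > 1L) {
    nc <- length(comm)
    # adjacency between communities
    best <- NULL
    for (i in seq_len(nc - 1L)) {
      for (j in (i + 1L):nc) {
        if (sum(Aact[comm[[i]], comm[[j]]]) <= 0) next
        d2 <- sum((profiles[[i]] - profiles[[j]])^2 / wk)
        ni <- length(comm[[i]]); nj <- length(comm[[j]])
        ds <- (ni * nj) / (ni + nj) * d2 / J
        if (is.null(best) || ds < best$ds) best <- list(i = i, j = j, ds = ds)
      }
    }
    if (is.null(best)) break  # only disconnected communities remain
    step <- step + 1L
    i <- best$i; j <- best$j
    ni <- length(comm[[i]]); nj <- length(comm[[j]])
    merged_profile <- (ni * profiles[[i]] + nj * profiles[[j]]) / (ni + nj)
    comm[[i]] <- c(comm[[i]], comm[[j]])
    profiles[[i]] <- merged_profile
    comm[[j]] <- NULL
    profiles[[j]] <- NULL
    trace[[step]] <- data.frame(step = step, c1 = i, c2 = j, dsigma = best$ds)
    levels[[step + 1L]] <- assignment_from(comm)
  }

  Q <- vapply(levels, function(asg) graph_modularity(A, asg), numeric(1))
  best_level <- which.max(Q)
  best <- levels[[best_level]]
  structure(list(assignment = best,
                 n_communities = length(unique(best[active])),
                 n_isolated = J - length(active),
                 modularity = Q[best_level],
                 merge_trace = if (length(trace)) do.call(rbind, trace)
                               else data.frame(step = integer(), c1 = integer(),
                                               c2 = integer(), dsigma = numeric()),
                 levels = levels,
                 level_modularity = Q),
            class = "walktrap_partition")
}

#' Weighted modularity of a partition
#'
#' `Q = sum_j (e_jj - a_j^2)` where `e_jj` is the fraction of total edge
#' weight inside community j and `a_j` the fraction of edge-end weight
#' attached to it. Zero for a single community; 0.5 for two equal
#' disconnected cliques split along components.
#'
#' @param net a `ggm_network` or weight matrix.
#' @param assignment community label per node (or a `walktrap_partition`).
#' @return scalar modularity.
#' @export
graph_modularity <- function(net, assignment) {
  A <- if (inherits(net, "ggm_network")) net$weights else as.matrix(net)
  if (inherits(assignment, "walktrap_partition")) assignment <- assignment$assignment
  W <- sum(A) / 2
  if (W <= 0) stop("network has zero total edge weight")
  labs <- unique(assignment)
  e_jj <- vapply(labs, function(l) {
    idx <- assignment == l
    sum(A[idx, idx]) / 2 / W
  }, numeric(1))
  a_j <- vapply(labs, function(l) {
    idx <- assignment == l
    sum(A[idx, ]) / (2 * W)
  }, numeric(1))
  sum(e_jj - a_j^2)
}

#' Exploratory graph analysis dimension count
#'
#' The number of factors is estimated as the number of communities in the
#' EBIC-tuned partial-correlation network under Walktrap clustering with
#' modularity selection. Because modularity penalizes single-community
#' solutions, a unidimensionality guard is applied first: an N x 4 block of
#' unidimensional data (single factor, loadings 0.70) is simulated, pushed
#' through the arm pipeline, and column-bound to the observed data. If the
#' combined (J+4)-variable solution has at most 2 communities the data are
#' declared unidimensional (1 factor); otherwise the pipeline is re-run on the
#' original J variables alone and its community count returned (singleton
#' communities of isolated nodes included).
#'
#' @param sample observed data in the arm's representation.
#' @param arm one element of [analysis_arms()].
#' @param gamma,n_lambda,lambda_min_ratio passed to [ebic_glasso()].
#' @param steps passed to [walktrap_partition()].
#' @return integer estimated number of factors.
#' @export
ega_count <- function(sample, arm, gamma = 0.5, n_lambda = 100L,
                      lambda_min_ratio = 0.01, steps = 4L) {
  N <- nrow(sample)
  R1 <- matrix(0.49, 4L, 4L)
  diag(R1) <- 1
  for (try in 1:100) {
    Zu <- draw_continuous_sample(R1, N)
    Du <- arm_transform(Zu, arm)
    if (.arm_data_ok(Du, arm)) break
    if (try == 100) stop("could not simulate a non-degenerate unidimensional block")
  }
  combined <- cbind(as.matrix(sample), Du)
  nc_comb <- .ega_pipeline(combined, arm, gamma, n_lambda, lambda_min_ratio, steps)
  if (nc_comb <= 2L) return(1L)
  .ega_pipeline(as.matrix(sample), arm, gamma, n_lambda, lambda_min_ratio, steps)
}

.ega_pipeline <- function(data, arm, gamma, n_lambda, lambda_min_ratio, steps) {
  S <- arm_correlation(data, arm)
  net <- ebic_glasso(S, n = nrow(data), gamma = gamma, n_lambda = n_lambda,
                     lambda_min_ratio = lambda_min_ratio)
  walktrap_partition(net, steps = steps)$n_communities
}

#' Export a network and partition as plain-text tables
#'
#' @param net a `ggm_network`.
#' @param partition a `walktrap_partition`.
#' @param edge_file,community_file output CSV paths.
#' @return invisibly, the two paths.
#' @export
export_network <- function(net, partition, edge_file, community_file) {
  pc <- net$partial_corr
  idx <- which(upper.tri(pc) & pc != 0, arr.ind = TRUE)
  edges <- data.frame(from = idx[, 1L], to = idx[, 2L],
                      partial_corr = pc[idx], weight = abs(pc[idx]))
  utils::write.csv(edges, edge_file, row.names = FALSE)
  comm <- data.frame(node = seq_along(partition$assignment),
                     community = partition$assignment)
  utils::write.csv(comm, community_file, row.names = FALSE)
  invisible(c(edge_file, community_file))
}
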
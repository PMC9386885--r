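test_that("glasso path satisfies the penalized-likelihood optimality conditions", {
  set.seed(10)
  S <- cor(matrix(rnorm(120 * 12), 120, 12))
  for (rho in c(0.02, 0.1, 0.3)) {
    K <- retsim:::.glasso_path_cpp(S, rho, maxit = 200, tol = 1e-6)$precision[, , 1]
    W <- solve(K)
    off <- upper.tri(S)
    nz <- off & abs(K) > 1e-8
    z <- off & abs(K) <= 1e-8
    expect_lt(max(abs(diag(W) - diag(S) - rho)), 1e-7)
    if (any(nz)) expect_lt(max(abs((S - W)[nz] + rho * sign(K[nz]))), 1e-6)
    if (any(z)) expect_lte(max(abs((S - W)[z])), rho + 1e-6)
    expect_gt(min(eigen(K, TRUE, TRUE)$values), 0)
  }
})

test_that("independent variables give an empty network", {
  net <- ebic_glasso(diag(8), n = 500)
  expect_equal(sum(net$weights), 0)
  expect_equal(net$strength, rep(0, 8))
})

test_that("block-structured correlations keep between-block edges at zero", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 0.6; S[5:8, 5:8] <- 0.6; diag(S) <- 1
  net <- ebic_glasso(S, n = 1000)
  expect_equal(max(net$weights[1:4, 5:8]), 0)
  expect_gt(min(net$weights[1:4, 1:4][upper.tri(diag(4))]), 0)
  # partial-correlation matrix: zero diagonal, symmetric, signed
  expect_equal(diag(net$partial_corr), rep(0, 8))
  expect_equal(net$weights, abs(net$partial_corr))
  expect_equal(net$strength, rowSums(net$weights))
})

test_that("EBIC-selected sparsity does not grow with n on a fixed sparse input", {
  S <- matrix(0, 9, 9)
  S[1:3, 1:3] <- 0.5; S[4:6, 4:6] <- 0.5; S[7:9, 7:9] <- 0.5; diag(S) <- 1
  edges <- vapply(c(500, 5000, 50000), function(n) {
    net <- ebic_glasso(S, n = n)
    sum(net$weights[upper.tri(S)] > 0)
  }, numeric(1))
  expect_true(all(diff(edges) <= 0) || max(edges) - min(edges) <= 1)
})

test_that("walktrap merges identical-profile nodes first and splits disconnected triangles", {
  # two disconnected triangles with unit weights
  A <- matrix(0, 6, 6)
  A[1:3, 1:3] <- 1; A[4:6, 4:6] <- 1; diag(A) <- 0
  part <- walktrap_partition(A)
  expect_equal(part$n_communities, 2L)
  expect_equal(length(unique(part$assignment[1:3])), 1L)
  expect_equal(length(unique(part$assignment[4:6])), 1L)
  expect_false(part$assignment[1] == part$assignment[4])
  # the selected level is the exhaustive-max over the trace
  expect_equal(part$modularity, best_modularity_exhaustive(A, part$levels))

  # nodes with identical adjacency rows have identical bare-walk profiles:
  # their walk distance (hence pairwise merge cost) is exactly 0, and the
  # selected partition keeps them together (lazy self-loops would separate
  # the profiles slightly, so the zero is checked on the plain walk)
  B <- matrix(0, 4, 4)
  B[1, 3] <- B[3, 1] <- 1; B[2, 3] <- B[3, 2] <- 1
  B[3, 4] <- B[4, 3] <- 0.5
  expect_equal(dsigma_direct(B, 1, 2, steps = 2, lazy = FALSE), 0)
  part2 <- walktrap_partition(B, steps = 2, lazy = FALSE)
  expect_equal(part2$assignment[1], part2$assignment[2])
})

test_that("ward-form merge cost equals the direct sum-of-squares evaluation", {
  set.seed(21)
  for (rep in 1:8) {
    A <- matrix(0, 6, 6)
    up <- upper.tri(A)
    vals <- runif(sum(up))
    vals[sample(length(vals), 6)] <- 0  # sparsify
    A[up] <- vals
    A <- A + t(A)
    if (all(rowSums(A) > 0)) {
      part <- walktrap_partition(A, steps = 4)
      # replay the merge trace, checking each recorded dsigma directly
      comms <- as.list(1:6)
      for (s in seq_len(nrow(part$merge_trace))) {
        mt <- part$merge_trace[s, ]
        direct <- dsigma_direct(A, comms[[mt$c1]], comms[[mt$c2]], steps = 4)
        expect_lt(abs(mt$dsigma - direct), 1e-10)
        comms[[mt$c1]] <- c(comms[[mt$c1]], comms[[mt$c2]])
        comms[[mt$c2]] <- NULL
      }
    }
  }
})

test_that("modularity closed forms hold", {
  A <- matrix(1, 4, 4); diag(A) <- 0
  expect_equal(graph_modularity(A, rep(1, 4)), 0)  # single community
  # two equal disconnected cliques split by component: Q = 0.5
  B <- matrix(0, 6, 6)
  B[1:3, 1:3] <- 1; B[4:6, 4:6] <- 1; diag(B) <- 0
  expect_equal(graph_modularity(B, rep(1:2, each = 3)), 0.5)
  expect_error(graph_modularity(matrix(0, 3, 3), rep(1, 3)), "zero total")
})

test_that("max-modularity level matches exhaustive search on small graphs", {
  set.seed(33)
  for (rep in 1:6) {
    A <- matrix(0, 6, 6)
    up <- upper.tri(A)
    A[up] <- rbinom(sum(up), 1, 0.5) * runif(sum(up), 0.2, 1)
    A <- A + t(A)
    if (any(A > 0)) {
      part <- walktrap_partition(A)
      expect_equal(part$modularity, best_modularity_exhaustive(A, part$levels))
    }
  }
})

test_that("walktrap agrees with an independent implementation on separated blocks", {
  skip_if_not_installed("igraph")
  set.seed(55)
  model <- block_population(0.8)
  Z <- draw_continuous_sample(model, 2000L)
  net <- ebic_glasso(pearson_matrix(Z), n = 2000L)
  part <- walktrap_partition(net, steps = 4)
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE)
  ref <- igraph::cluster_walktrap(g, steps = 4)
  expect_equal(part$n_communities, length(unique(igraph::membership(ref))))
})

test_that("EGA recovers block structure and the unidimensional guard", {
  model <- block_population(0.8)
  arm <- analysis_arms()$cont_pearson
  hits <- vapply(1:10, function(r) {
    set.seed(900 + r)
    Z <- draw_continuous_sample(model, 1000L)
    ega_count(Z, arm)
  }, numeric(1))
  expect_gte(mean(hits == 3), 0.9)

  R1 <- matrix(0.49, 8, 8); diag(R1) <- 1
  ones <- vapply(1:10, function(r) {
    set.seed(950 + r)
    Z <- draw_continuous_sample(R1, 1000L)
    ega_count(Z, arm)
  }, numeric(1))
  expect_true(all(ones == 1))
})

test_that("network and partition export as readable edge/community tables", {
  S <- matrix(0, 8, 8)
  S[1:4, 1:4] <- 0.6; S[5:8, 5:8] <- 0.6; diag(S) <- 1
  net <- ebic_glasso(S, n = 1000)
  part <- walktrap_partition(net)
  dir <- withr::local_tempdir()
  export_network(net, part, file.path(dir, "edges.csv"),
                 file.path(dir, "comm.csv"))
  edges <- utils::read.csv(file.path(dir, "edges.csv"))
  expect_true(all(edges$weight == abs(edges$partial_corr)))
  expect_true(all(edges$from < edges$to))
  comm <- utils::read.csv(file.path(dir, "comm.csv"))
  expect_equal(comm$community, part$assignment)
})

test_that("EGA on population block matrices equals the block count", {
  arm <- analysis_arms()$cont_pearson
  for (blocks in 2:4) {
    J <- blocks * 5L
    R <- matrix(0, J, J)
    for (b in seq_len(blocks)) {
      idx <- ((b - 1) * 5 + 1):(b * 5)
      R[idx, idx] <- 0.5
    }
    diag(R) <- 1
    set.seed(blocks)
    Z <- draw_continuous_sample(R, 5000L)
    expect_equal(ega_count(Z, arm), blocks)
  }
})
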
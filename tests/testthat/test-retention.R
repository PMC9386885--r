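test_that("eigen spectra of structured matrices match closed forms", {
  expect_equal(eigen_spectrum(diag(5)), rep(1, 5))
  eq <- matrix(0.5, 3, 3); diag(eq) <- 1
  expect_equal(eigen_spectrum(eq), c(2, 0.5, 0.5))
  R <- random_corr(8, seed = 3)
  expect_lt(abs(sum(eigen_spectrum(R)) - 8), 1e-8)
  bad <- R; bad[1, 2] <- bad[1, 2] + 1
  expect_error(eigen_spectrum(bad), "symmetric")
})

test_that("kaiser count uses a strict inequality", {
  expect_equal(kaiser_count(rep(1, 5)), 0)          # exactly 1 not counted
  expect_equal(kaiser_count(c(2, 0.5, 0.5)), 1)
  expect_equal(kaiser_count(c(3, 2.5, 1.000001, 0.2)), 3)
})

test_that("acceleration factor finds the elbow by second differences", {
  # af at i=2,3,4 -> (0.5, 1.45, 0), max at i=3 -> retain 2
  expect_equal(acceleration_factor(c(4, 2, 0.5, 0.45, 0.4)), 2)
  # max at i=4 -> retain 3
  expect_equal(acceleration_factor(c(3, 2.9, 2.8, 0.2, 0.1, 0.05)), 3)
  # strictly linear spectrum (exact integers): all af = 0, first-index
  # tie-break -> 1
  expect_equal(acceleration_factor(c(6, 5, 4, 3, 2, 1)), 1)
  expect_error(acceleration_factor(c(2, 1)), "at least 3")
})

test_that("kaiser combination takes the minimum", {
  expect_equal(combine_with_kaiser(2, 1), 1)
  expect_equal(combine_with_kaiser(3, 5), 3)
  expect_equal(combine_with_kaiser(0, 4), 0)
})

test_that("parallel analysis retains strong factors and rejects pure noise", {
  arm <- analysis_arms()$cont_pearson
  R1 <- matrix(0.81, 6, 6); diag(R1) <- 1  # single factor, loadings 0.9
  hits <- vapply(1:20, function(r) {
    set.seed(600 + r)
    Z <- draw_continuous_sample(R1, 1000L)
    parallel_analysis(Z, arm, reference = "p95")
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.95)

  nulls <- vapply(1:30, function(r) {
    set.seed(700 + r)
    Z <- matrix(rnorm(500 * 20), 500, 20)
    parallel_analysis(Z, arm, reference = "p95")
  }, numeric(1))
  expect_gte(mean(nulls == 0), 0.8)
})

test_that("an observed spectrum equal to its reference retains nothing", {
  # strict inequality at the boundary: feed the reference as observation
  expect_equal(retsim:::.sequential_count(c(2, 1, 0.5), c(2, 1, 0.5)), 0)
  expect_equal(retsim:::.sequential_count(c(2.1, 1, 0.5), c(2, 1, 0.5)), 1)
  # stop at first failure even if later eigenvalues pass
  expect_equal(retsim:::.sequential_count(c(2.1, 0.9, 0.7), c(2, 1, 0.5)), 1)
})

test_that("revised parallel analysis stage 0 matches traditional PA on the first eigenvalue", {
  arm <- analysis_arms()$cont_pearson
  set.seed(31)
  Z <- matrix(rnorm(200 * 8), 200, 8)  # pure noise: both should say 0 almost surely
  set.seed(1); rpa <- revised_parallel_analysis(Z, arm)
  set.seed(1); pa <- parallel_analysis(Z, arm, reference = "p95")
  expect_equal(rpa, 0)
  expect_equal(pa, 0)
})

test_that("revised parallel analysis recovers a strong single factor", {
  arm <- analysis_arms()$cont_pearson
  R1 <- matrix(0.81, 6, 6); diag(R1) <- 1
  hits <- vapply(1:20, function(r) {
    set.seed(800 + r)
    Z <- draw_continuous_sample(R1, 1000L)
    revised_parallel_analysis(Z, arm)
  }, numeric(1))
  expect_gte(mean(hits == 1), 0.95)
})

test_that("implied m-factor matrices are proper correlation matrices", {
  R <- unclass_matrix_plain(pearson_matrix(
    draw_continuous_sample(block_population(), 300L)))
  for (model in c("efa", "pca")) {
    for (m in c(0L, 1L, 3L, 5L)) {
      implied <- implied_correlation(R, m, model = model)
      expect_equal(diag(implied), rep(1, 20), tolerance = 1e-8,
                   ignore_attr = TRUE)
      expect_gt(min(eigen(implied, TRUE, TRUE)$values), 0)
    }
  }
  expect_identical(implied_correlation(R, 0L), diag(20))
})

test_that("map statistic matches the brute-force double loop", {
  for (seed in 1:5) {
    R <- random_corr(6, seed = seed)
    for (m in 0:3) {
      expect_lt(abs(map_statistic(R, m) - map_statistic_bruteforce(R, m)),
                1e-12)
    }
  }
})

test_that("map statistic closed forms and bounds", {
  expect_equal(map_statistic(diag(4), 0), 0)
  eq <- matrix(0.5, 3, 3); diag(eq) <- 1
  expect_equal(map_statistic(eq, 0), 0.25)
  # partialing a spurious component out of a near-null matrix induces partials
  near_null <- matrix(0.05, 4, 4); diag(near_null) <- 1
  expect_gt(map_statistic(near_null, 1), 0)
  expect_error(map_statistic(diag(4), 3), "m must lie")
  # exactly-identity input aligns the component with an axis: degenerate
  expect_error(map_statistic(diag(4), 1), "degenerate")
})

test_that("map count finds block structure and the zero rule", {
  expect_equal(map_count(diag(4)), 0)  # f0 = 0 < f1
  model <- block_population(loading = 0.8)
  expect_equal(map_count(model$R), 3)
  for (seed in 6:9) {
    R <- random_corr(7, seed = seed)
    m <- map_count(R)
    expect_gte(m, 0); expect_lte(m, 5)
  }
})
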
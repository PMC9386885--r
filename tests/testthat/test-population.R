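test_that("major loadings have perfect simple structure and near-equal blocks", {
  set.seed(1)
  spec <- population_spec(n_items = 6L, n_major = 3L,
                          communality_levels = 0.49, seed = 1L)
  maj <- build_major_loadings(spec)
  expect_equal(dim(maj$Lambda), c(6L, 3L))
  expect_equal(colSums(maj$Lambda != 0), c(2L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(maj$Lambda[maj$Lambda != 0], rep(0.7, 6))

  spec20 <- study_spec("low")
  maj20 <- build_major_loadings(spec20)
  expect_equal(as.vector(table(maj20$block)), c(7L, 7L, 6L))
  expect_true(all(rowSums(maj20$Lambda != 0) == 1))
  # row sums of squares equal the sampled communalities exactly
  expect_equal(rowSums(maj20$Lambda^2), maj20$h2)
  expect_true(all(maj20$h2 %in% c(0.2, 0.3, 0.4)))
})

test_that("spec validation rejects impossible designs", {
  expect_error(population_spec(n_items = 2L, n_major = 3L), "n_items")
  expect_error(population_spec(communality_levels = c(0.2, 1.0)), "communality")
  expect_error(population_spec(common_ratio = 0), "common_ratio")
  expect_error(population_spec(interfactor_corr = 1), "interfactor_corr")
})

test_that("minor loadings decay geometrically and carry the minor communality", {
  spec <- study_spec("low")
  set.seed(5)
  maj <- build_major_loadings(spec)
  mino <- build_minor_loadings(spec, maj$h2)
  # h2_minor = 0.25 * (1 - h2_major): e.g. 0.36 -> 0.16, psi 0.48
  expect_equal(mino$h2, 0.25 * (1 - maj$h2))
  expect_equal(rowSums(mino$Lambda^2), mino$h2)
  # column scale follows common_ratio^(m-1) in expectation; check the exact
  # multiplier by regenerating with an identical stream
  set.seed(99)
  G <- matrix(rnorm(spec$n_items * spec$n_minor), spec$n_items, spec$n_minor)
  set.seed(99)
  mino2 <- build_minor_loadings(spec, maj$h2)
  scaled <- sweep(G, 2L, spec$common_ratio^(seq_len(spec$n_minor) - 1L), `*`)
  expect_equal(mino2$Lambda,
               scaled * sqrt(mino2$h2) / sqrt(rowSums(scaled^2)))
})

test_that("minor communality of 0.36-major item follows the quarter rule", {
  spec <- population_spec(n_items = 4L, n_major = 2L, n_minor = 10L,
                          communality_levels = 0.36, seed = 3L)
  model <- assemble_population(spec)
  expect_equal(model$h2_minor, rep(0.25 * (1 - 0.36), 4))
  expect_equal(model$psi, rep(0.48, 4))
})

test_that("assembled population satisfies the correlation-matrix identities", {
  # M2 = 0, orthogonal factors: R[1,2] = product of same-factor loadings
  spec <- population_spec(n_items = 4L, n_major = 2L, n_minor = 0L,
                          communality_levels = 0.49, seed = 2L)
  model <- assemble_population(spec)
  expect_equal(model$R[1, 2], 0.49, tolerance = 1e-12)
  expect_equal(model$R[1, 3], 0, tolerance = 1e-12)  # different factors

  # correlated factors: cross-block entry = l1 * theta * l2
  spec2 <- population_spec(n_items = 4L, n_major = 2L, n_minor = 0L,
                           communality_levels = 0.49,
                           interfactor_corr = 0.5, seed = 2L)
  model2 <- assemble_population(spec2)
  expect_equal(model2$R[1, 3], 0.7 * 0.5 * 0.7, tolerance = 1e-12)
})

test_that("full-design populations are proper correlation matrices", {
  for (comm in c("low", "high")) {
    for (theta in c(0, 0.5)) {
      for (seed in c(1L, 77L, 1234L)) {
        model <- assemble_population(study_spec(comm, theta, seed))
        expect_lt(max(abs(diag(model$R) - 1)), 1e-10)
        expect_gt(min(eigen(model$R, TRUE, TRUE)$values), 0)
        expect_lt(max(abs(model$h2_major + model$h2_minor + model$psi - 1)),
                  1e-10)
        expect_true(all(model$psi > 0))
        expect_true(all(rowSums(model$Lambda_major != 0) == 1))
      }
    }
  }
})

test_that("M2 = 0 recovers the textbook common-factor correlation matrix", {
  model <- block_population(loading = 0.8, theta = 0)
  L <- model$Lambda_major
  R_theory <- L %*% t(L)
  diag(R_theory) <- 1
  # psi absorbs minor share even with M2 = 0, so rebuild from the definition
  expect_equal(unclass(model$R - (L %*% t(L) + diag(model$psi + model$h2_minor))),
               matrix(0, 20, 20) - diag(0, 20), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(model$h2_minor, rep(0, 20))
})

test_that("population JSON round-trip preserves the model", {
  model <- assemble_population(study_spec("high", 0.5, seed = 9L))
  path <- withr::local_tempfile(fileext = ".json")
  population_to_json(model, path)
  back <- population_from_json(path)
  expect_equal(back$R, model$R, ignore_attr = TRUE)
  expect_equal(back$psi, model$psi)
  expect_equal(back$spec$seed, model$spec$seed)
})

test_that("the population draw is fixed by the spec seed", {
  a <- assemble_population(study_spec("low", 0, seed = 42L))
  b <- assemble_population(study_spec("low", 0, seed = 42L))
  c <- assemble_population(study_spec("low", 0, seed = 43L))
  expect_identical(a$R, b$R)
  expect_false(isTRUE(all.equal(a$R, c$R)))
})
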
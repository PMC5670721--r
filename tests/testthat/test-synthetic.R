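test_that("AR(1) covariance has the stated entries and is positive definite", {
  V <- ar1_covariance(3, 0.5)
  expect_equal(diag(V), rep(1, 3))
  expect_equal(V[1, 3], 0.25)
  expect_equal(V[2, 1], 0.5)
  expect_true(all(eigen(ar1_covariance(200, 0.5),
                        symmetric = TRUE, only.values = TRUE)$values > 0))
  expect_error(ar1_covariance(3, 1), "rho")
})

test_that("built-in settings induce the printed gene-level coefficients", {
  s1 <- simulation_setting(1, p = 20)
  expect_equal(s1$beta, c(1.5, -0.5, -0.5, -0.5, rep(0, 16)))
  s2 <- simulation_setting(2, p = 20)
  expect_equal(s2$beta, c(1.5, -1.5, -0.5, 0.5, rep(0, 16)))
  s3 <- simulation_setting(3, p = 20)
  expect_equal(s3$beta, c(2, -1, -0.5, -0.5, rep(0, 16)))
  expect_false(c(is_min_l1_pairs(s1$alpha)))
  expect_true(c(is_min_l1_pairs(s2$alpha)))
  expect_false(c(is_unique_min_l1(s2$alpha)))
  expect_true(c(is_unique_min_l1(s3$alpha)))
  expect_error(simulation_setting(1, p = 3), "p >= 4")
  expect_error(simulation_setting(5), "setting_id")
})

test_that("dataset generation is seed-deterministic with the right shapes", {
  st <- simulation_setting(1, p = 20, n = 50)
  d1 <- generate_dataset(st, 50, seed = 9)
  expect_equal(dim(d1$log_expr), c(50L, 20L))
  expect_length(d1$response, 50)
  d2 <- generate_dataset(st, 50, seed = 9)
  expect_identical(d1$log_expr, d2$log_expr)
  expect_identical(d1$response, d2$response)
  d3 <- generate_dataset(st, 50, seed = 10)
  expect_false(identical(d1$log_expr, d3$log_expr))
  # the generator does not disturb the session RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_dataset(st, 5, seed = 3)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("large-sample moments match the generative model", {
  st <- simulation_setting(1, p = 10, n = 50, sigma = 0.5)
  d <- generate_dataset(st, 100000, seed = 77)
  emp <- cov(d$log_expr)
  expect_lt(max(abs(emp - ar1_covariance(10, 0.5))), 0.02)
  V <- ar1_covariance(10, 0.5)
  expected_var <- drop(st$beta %*% V %*% st$beta) + 0.5^2
  expect_equal(var(d$response), expected_var, tolerance = 0.03)
})

test_that("dense centered problems sum to zero and peel consistently", {
  d <- generate_dense_beta_dataset(20, 50, seed = 13)
  expect_lt(abs(sum(d$true_beta)), 1e-12)
  expect_equal(dim(d$log_expr), c(50L, 20L))
  expect_equal(beta_from_alpha(d$true_alpha), d$true_beta,
               tolerance = 1e-10)
  d2 <- generate_dense_beta_dataset(20, 50, seed = 13)
  expect_identical(d$response, d2$response)
})

test_that("sample shifts move row means but not sum-to-zero predictions", {
  withr::local_seed(88)
  X <- matrix(rnorm(200), 20, 10)
  Xs <- apply_sample_shifts(X, seed = 5)
  shifts <- attr(Xs, "shifts")
  expect_equal(rowMeans(Xs) - rowMeans(X), shifts)
  beta <- random_centered_beta(10)
  expect_equal(drop(Xs %*% beta), drop(X %*% beta), tolerance = 1e-12)
  # a non-centered coefficient vector is NOT invariant
  bc <- beta + 0.3
  expect_gt(max(abs(Xs %*% bc - X %*% bc)), 0.01)
})

test_that("random rescaling is positive, recorded, and rank-1 in log space", {
  withr::local_seed(99)
  E <- matrix(rexp(60) + 0.1, 6, 10)
  expect_equal(apply_random_scaling(E, FALSE, FALSE, seed = 1), E,
               ignore_attr = TRUE)
  Es <- apply_random_scaling(E, TRUE, TRUE, seed = 2)
  gf <- attr(Es, "gene_factors"); sf <- attr(Es, "sample_factors")
  expect_true(all(gf > 0) && all(sf > 0))
  expect_equal(log(Es), log(E) + outer(log(gf), log(sf), `+`),
               ignore_attr = TRUE, tolerance = 1e-12)
  E[1, 1] <- 0
  expect_error(apply_random_scaling(E, TRUE, TRUE, seed = 3), "positive")
})
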
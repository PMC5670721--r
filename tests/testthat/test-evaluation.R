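test_that("prediction and estimation metrics follow their definitions", {
  y <- c(0, 2); expect_equal(mse(y, c(1, 1)), 1)
  expect_equal(mse(y, y), 0)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(c(1, 2, 3), rep(2, 3)), 0)
  expect_error(mse(1:3, 1:2), "lengths differ")

  expect_equal(relative_error(c(3, 4), c(3, 4)), 0)
  expect_equal(relative_error(c(0, 0), c(3, 4)), 1)
  expect_equal(relative_error(c(0, 4), c(3, 4)), 0.6)
  expect_error(relative_error(c(0, 0), c(0, 0)), "all zero")
})

test_that("false identification rate counts the top-|support| overlap", {
  truth <- c(2, 0, -1, 0, 0.5)
  expect_equal(false_rate(c(1.9, 0, -1.2, 0, 0.1), truth), 0)
  expect_equal(false_rate(c(0, 5, 0, 4, 0), truth), 1)
  # |support| = 3, overlap 2 -> 1/3
  expect_equal(false_rate(c(2, 3, -1, 0, 0), truth), 1 / 3)
  # invariant to positive rescaling of the estimate
  withr::local_seed(7)
  est <- rnorm(5)
  expect_equal(false_rate(est, truth), false_rate(10 * est, truth))
  expect_equal(false_rate(est, truth), false_rate(est / 977, truth))
  # an exactly zero coefficient identifies nothing
  expect_equal(false_rate(rep(0, 5), truth), 1)
  expect_error(false_rate(est, rep(0, 5)), "support")
})

test_that("small convergence benchmarks succeed against the reference", {
  b <- benchmark_convergence(10, 40, n_replicates = 3, base_seed = 21)
  expect_equal(b$success_rate, 100)
  expect_true(all(b$replicates$converged))
  expect_true(all(b$replicates$constraint_violation <= 1e-8))
  expect_equal(nrow(b$replicates), 3L)

  # vacuous tolerances cannot fail
  loose <- success_criteria(constraint_tol = 1e6, solution_tol = 1e6,
                            solver_precision = 1e-4)
  b2 <- benchmark_convergence(6, 12, n_replicates = 2, base_seed = 22,
                              criteria = loose)
  expect_equal(b2$success_rate, 100)
})

test_that("the accuracy benchmark favors the constrained fit under shifts", {
  lams <- lambda_grid(100, 1e-4, 40)
  b <- benchmark_accuracy(3, p = 10, n = 30, sigma = 0.5,
                          n_replicates = 3, base_seed = 31, lambdas = lams)
  expect_equal(b$n_excluded, 0L)
  s <- b$summary
  expect_setequal(s$method, c("proposed", "lasso1", "lasso2"))
  expect_true(all(is.finite(unlist(s[, -1]))))
  # sample-wise shifts on the validation set penalize the unconstrained
  # gene-level fit but not the sum-to-zero fit
  r <- b$replicates
  prop <- r[r$method == "proposed", ]
  l2 <- r[r$method == "lasso2", ]
  expect_true(all(prop$mse <= l2$mse))
  expect_true(all(prop$fr >= 0 & prop$fr <= 1))
})

test_that("pair-coefficient collapse preserves predictions exactly", {
  withr::local_seed(41)
  p <- 7; n <- 15
  X <- matrix(rnorm(n * p), n, p)
  Z <- build_pair_design(X)
  pairs <- t(attr(Z, "pairs"))
  amat <- matrix(rnorm(ncol(Z) * 3), ncol(Z), 3)
  Bg <- pairzero:::collapse_pair_beta(amat, p, pairs)
  expect_equal(X %*% Bg, Z %*% amat, tolerance = 1e-12)
  expect_equal(colSums(Bg), rep(0, 3), tolerance = 1e-12)
})
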
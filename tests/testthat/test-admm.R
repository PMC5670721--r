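tight <- admm_control(eps_abs = 1e-10, eps_rel = 1e-10)

test_that("soft threshold shrinks elementwise", {
  expect_equal(soft_threshold(c(1.2, 0.3, -1), 0.5), c(0.7, 0, -0.5))
  v <- c(-2, 0, 3.5)
  expect_equal(soft_threshold(v, 0), v)
  expect_equal(soft_threshold(0.4, 0.4), 0)
  expect_error(soft_threshold(1, -0.1), "non-negative")
})

test_that("two-gene constrained fit matches the scalar closed form", {
  # with design I_2, response (1, -1) and beta = (t, -t), the objective is
  # (1 - t)^2 + 2 lambda |t|, minimized at t = 1 - lambda
  pr <- constrained_lasso_problem(diag(2), c(1, -1))
  f <- admm_fit(pr, 0.4, tight)
  expect_true(f$converged)
  expect_equal(f$coefficients, c(0.6, -0.6), tolerance = 1e-8)
})

test_that("lambda_max zeroes the fit and defines the grid", {
  expect_equal(lambda_max(constrained_lasso_problem(cbind(c(1, 1)), c(2, 2),
                                                    constrained = FALSE)), 4)
  expect_error(lambda_max(constrained_lasso_problem(diag(3), rep(0, 3))),
               "degenerate")
  withr::local_seed(11)
  A <- matrix(rnorm(15), 5, 3); b <- rnorm(5)
  pr <- constrained_lasso_problem(A, b)
  expect_equal(lambda_max(pr), max(abs(t(A) %*% b)))
  f <- admm_fit(pr, lambda_max(pr), tight)
  expect_equal(f$z, rep(0, 3))

  expect_equal(lambda_grid(100, 0.01, 3), c(100, 10, 1))
  expect_equal(lambda_grid(7, 0.5, 2), c(7, 3.5))
  g <- lambda_grid(1e4, 1e-6, 100)
  expect_length(g, 100)
  expect_equal(g[1], 1e4)
  expect_equal(g[100], 1e-2)
  expect_true(all(diff(log(g)) < 0))
  expect_equal(diff(log(g)), rep(diff(log(g))[1], 99)) # uniform in log
  expect_error(lambda_grid(1, 0.1, 1), "at least 2")
})

test_that("converged solutions match the reference optimum", {
  withr::local_seed(22)
  for (i in 1:12) {
    pr <- random_problem(p = sample(c(5, 20), 1), n = sample(c(10, 100), 1))
    lam <- runif(1, 0.1, 2)
    f <- admm_fit(pr, lam, tight)
    ref <- reference_solution(pr, lam)
    expect_true(f$converged)
    expect_lte(abs(f$objective - ref$objective), 1e-6)
    expect_lte(abs(sum(f$coefficients)), 1e-10)
  }
})

test_that("both factorization branches solve the same problem identically", {
  # appending zero rows changes only the branch (rows vs columns), not the
  # optimization problem
  withr::local_seed(33)
  p <- 12; n <- 8
  X <- matrix(rnorm(n * p), n, p); y <- rnorm(n)
  pr_lemma <- constrained_lasso_problem(X, y) # 9 rows of E < 12 cols
  pr_direct <- constrained_lasso_problem(rbind(X, matrix(0, 6, p)),
                                         c(y, rep(0, 6)))
  f1 <- admm_fit(pr_lemma, 0.7, tight)
  f2 <- admm_fit(pr_direct, 0.7, tight)
  expect_true(f1$lemma_branch)
  expect_false(f2$lemma_branch)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("warm-started paths start empty, are deterministic, and overfit monotonically", {
  withr::local_seed(44)
  pr <- random_problem(p = 10, n = 40)
  pa <- solve_path(pr, control = tight, nlambda = 30)
  expect_equal(unname(pa$beta[, 1]), rep(0, 10)) # all zero at lambda_max
  expect_true(all(pa$converged))
  # training MSE is non-increasing as the penalty decreases
  fitted_mse <- colMeans((pr$design %*% pa$beta - pr$response)^2)
  expect_true(all(diff(fitted_mse) <= 1e-10))
  # deterministic: a second run is bit-identical
  pa2 <- solve_path(pr, control = tight, nlambda = 30)
  expect_identical(pa$beta, pa2$beta)
  # constraint feasible along the whole path
  expect_true(all(abs(colSums(pa$beta)) <= 1e-8))
})

test_that("unconstrained fits agree with glmnet", {
  skip_if_not_installed("glmnet")
  withr::local_seed(55)
  n <- 40; p <- 8
  X <- matrix(rnorm(n * p), n, p); y <- rnorm(n)
  pr <- constrained_lasso_problem(X, y, constrained = FALSE)
  for (lam in c(2, 0.5, 0.1)) {
    ours <- unconstrained_fit(pr, lam, tight)
    gn <- glmnet::glmnet(X, y, lambda = lam / n, standardize = FALSE,
                         intercept = FALSE, thresh = 1e-14)
    expect_equal(ours$coefficients, as.numeric(gn$beta), tolerance = 1e-5)
  }
  # orthonormal design: closed form is one soft threshold of A^T b
  Q <- qr.Q(qr(matrix(rnorm(100), 10, 10)))[, 1:4]
  y2 <- rnorm(10)
  pr2 <- constrained_lasso_problem(Q, y2, constrained = FALSE)
  f <- unconstrained_fit(pr2, 0.3, tight)
  expect_equal(f$coefficients, soft_threshold(drop(t(Q) %*% y2), 0.3),
               tolerance = 1e-8)
})

test_that("pair design columns are lexicographic log-ratios", {
  r <- build_pair_design(matrix(c(0, 1, 3), 1, 3))
  expect_equal(drop(r), c(-1, -3, -2), ignore_attr = TRUE)
  expect_equal(ncol(build_pair_design(matrix(0, 2, 2))), 1L)
  expect_equal(ncol(build_pair_design(matrix(0, 3, 5))), 10L)
  expect_error(build_pair_design(matrix(0, 3, 1)), "two genes")
  X <- matrix(rnorm(12), 3, 4)
  Z <- build_pair_design(X)
  pairs <- attr(Z, "pairs")
  for (c in seq_len(ncol(Z)))
    expect_equal(Z[, c], X[, pairs[c, 1]] - X[, pairs[c, 2]])
})

test_that("solution paths are invariant to per-sample and per-gene rescaling", {
  withr::local_seed(66)
  n <- 30; p <- 8
  X <- matrix(rnorm(n * p), n, p); y <- rnorm(n)
  lams <- lambda_grid(lambda_max(constrained_lasso_problem(X, y)), 0.05, 20)

  # per-sample scaling of raw expression = per-row shift of the log design;
  # the constrained path does not move
  shifts <- rnorm(n)
  p1 <- solve_path(constrained_lasso_problem(X, y), lams, tight)
  p2 <- solve_path(constrained_lasso_problem(X + shifts, y), lams, tight)
  expect_equal(p1$beta, p2$beta, tolerance = 1e-8)
  expect_identical(p1$beta != 0, p2$beta != 0)

  # per-gene scaling = per-column shift; with an intercept the constrained
  # path is again unmoved (the intercept absorbs the constant)
  gshift <- rnorm(p)
  p3 <- solve_path(constrained_lasso_problem(X, y, intercept = TRUE),
                   lams, tight)
  p4 <- solve_path(constrained_lasso_problem(sweep(X, 2, gshift, `+`), y,
                                             intercept = TRUE), lams, tight)
  expect_equal(p3$beta, p4$beta, tolerance = 1e-8)
})
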
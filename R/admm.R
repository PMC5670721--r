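#' Soft-thresholding operator
#'
#' Elementwise shrinkage `sign(v) * pmax(|v| - t, 0)`, the proximal operator
#' of the L1 norm used in the ADMM z-update.
#'
#' @param v Numeric vector.
#' @param t Non-negative threshold (scalar or vector recycled over `v`).
#' @return Numeric vector of the same length as `v`.
#' @examples
#' soft_threshold(c(1.2, 0.3, -1), 0.5) # (0.7, 0, -0.5)
#' @export
soft_threshold <- function(v, t) {
  if (any(t < 0)) stop("threshold 't' must be non-negative")
  sign(v) * pmax(abs(v) - t, 0)
}

#' Constrained lasso problem
#'
#' Bundles a design matrix of log expressions, a continuous response, and the
#' sum-to-zero equality constraint into the form the ADMM solver consumes:
#' minimize \eqn{\tfrac12\|Ax - b\|_2^2 + \lambda\|x\|_1} subject to
#' \eqn{Cx = d}. With `intercept = TRUE` an all-ones column is prepended; the
#' intercept is neither penalized nor constrained (its entry in `C` is 0).
#' With `constrained = FALSE` the equality constraint is dropped and the
#' problem is an ordinary lasso — used for the pair-design and log-design
#' baselines.
#'
#' @param design Numeric matrix (samples x predictors), typically log
#'   expression values or pairwise log-ratios from [build_pair_design()].
#' @param response Numeric response vector, one value per sample.
#' @param intercept Include an unpenalized, unconstrained intercept column?
#'   Default `FALSE` (generative models in the simulations are mean-zero);
#'   the expression pipeline turns it on.
#' @param constrained Impose the sum-to-zero constraint on the (non-intercept)
#'   coefficients? Default `TRUE`.
#' @param constraint_value Right-hand side `d` of the equality constraint
#'   (default 0, the sum-to-zero model).
#' @return An object of class `constrained_lasso_problem`: list with
#'   `design` (including any intercept column), `response`,
#'   `constraint_row`, `constraint_value`, `penalize`, `intercept`,
#'   `constrained`, and `varnames` (non-intercept column names).
#' @export
constrained_lasso_problem <- function(design, response, intercept = FALSE,
                                      constrained = TRUE,
                                      constraint_value = 0) {
  design <- as.matrix(design)
  response <- as.numeric(response)
  if (!is.numeric(design) || anyNA(design) || any(!is.finite(design)))
    stop("'design' must be a finite numeric matrix")
  if (nrow(design) != length(response))
    stop("nrow(design) must equal length(response)")
  if (any(!is.finite(response))) stop("'response' must be finite")
  varnames <- colnames(design)
  if (is.null(varnames)) varnames <- paste0("V", seq_len(ncol(design)))
  if (intercept) {
    design <- cbind(`(Intercept)` = 1, design)
    constraint_row <- c(0, rep(1, ncol(design) - 1L))
    penalize <- c(FALSE, rep(TRUE, ncol(design) - 1L))
  } else {
    constraint_row <- rep(1, ncol(design))
    penalize <- rep(TRUE, ncol(design))
  }
  if (!constrained) constraint_row <- rep(0, ncol(design))
  structure(list(design = design, response = response,
                 constraint_row = constraint_row,
                 constraint_value = if (constrained) constraint_value else 0,
                 penalize = penalize, intercept = intercept,
                 constrained = constrained, varnames = varnames),
            class = "constrained_lasso_problem")
}

#' @export
print.constrained_lasso_problem <- function(x, ...) {
  cat(sprintf(
    "Constrained lasso problem: %d sample(s) x %d coefficient(s)%s%s\n",
    nrow(x$design), ncol(x$design),
    if (x$intercept) " (incl. intercept)" else "",
    if (x$constrained) ", sum-to-zero constraint" else ", unconstrained"))
  invisible(x)
}

#' ADMM control parameters
#'
#' @param rho Positive augmented-Lagrangian penalty parameter, or `NULL`
#'   (default) to scale it with the penalty level and the data as
#'   \eqn{\rho = \max(\lambda, \overline{\mathrm{diag}}(A^T A))}, the mean
#'   squared column norm of the design. Any positive value converges to the
#'   same solution; the scaled choice keeps the soft-threshold step
#'   \eqn{\lambda/\rho} and the quadratic term on comparable scales across
#'   wide penalty grids, cutting iteration counts severalfold. When `rho`
#'   changes along a path the cached factorization is recomputed and the
#'   scaled duals are rescaled, so warm starts remain exact.
#' @param eps_abs Absolute stopping tolerance (default `1e-6`; convergence
#'   benchmarks override this with the tighter precision they state).
#' @param eps_rel Relative stopping tolerance (default `1e-4`).
#' @param max_iter Maximum ADMM iterations per lambda (default `1e5`).
#' @return A list of class `admm_control`.
#' @export
admm_control <- function(rho = NULL, eps_abs = 1e-6, eps_rel = 1e-4,
                         max_iter = 100000L) {
  stopifnot(is.null(rho) || rho > 0, eps_abs > 0, eps_rel > 0, max_iter >= 1)
  structure(list(rho = rho, eps_abs = eps_abs, eps_rel = eps_rel,
                 max_iter = as.integer(max_iter)), class = "admm_control")
}

# per-lambda rho values implied by a control list and the design scale
rho_for <- function(control, lambdas, design) {
  if (is.null(control$rho)) {
    pmax(lambdas, mean(colSums(design^2)))
  } else {
    rep(control$rho, length(lambdas))
  }
}

#' Objective value of the (constrained) lasso problem at a coefficient vector
#'
#' \eqn{\tfrac12\|Ax - b\|_2^2 + \lambda \sum_{j \in P} |x_j|} with the sum
#' over penalized coordinates only.
#'
#' @param problem A [constrained_lasso_problem].
#' @param x Coefficient vector (including intercept position, if any).
#' @param lambda Penalty level.
#' @return Scalar objective value.
#' @export
lasso_objective <- function(problem, x, lambda) {
  r <- problem$design %*% x - problem$response
  0.5 * sum(r^2) + lambda * sum(abs(x[problem$penalize]))
}

#' Fit the constrained lasso at one penalty level by ADMM
#'
#' Solves the split reformulation with an x-update from a cached Cholesky
#' factorization (via the matrix inversion lemma when there are fewer rows
#' than coefficients), a soft-threshold z-update, and a scaled dual update,
#' stopping when primal and dual residual norms fall below their combined
#' absolute/relative tolerances. Non-convergence within `max_iter` returns
#' the current iterate with `converged = FALSE` and a warning.
#'
#' @param problem A [constrained_lasso_problem].
#' @param lambda Non-negative penalty level.
#' @param control An [admm_control] list.
#' @param warm Optional `admm_solution` (or the `warm` element of one) used
#'   to initialize `x`, `z` and the duals — e.g. the previous solution on a
#'   decreasing lambda path.
#' @return An object of class `admm_solution`: `coefficients` (the solution
#'   of record — the primal iterate with its residual constraint violation
#'   spread over the constrained coefficients so the equality holds
#'   exactly; equal to the sparse `z` iterate for unconstrained problems),
#'   `x` (raw primal), `z` (split copy, exactly sparse), `u1`/`u2` (scaled
#'   duals), `iterations`, `primal_residual`, `dual_residual`, `converged`,
#'   `lambda`, `objective` (at `coefficients`).
#' @examples
#' pr <- constrained_lasso_problem(diag(2), c(1, -1))
#' round(admm_fit(pr, 0.4, admm_control(eps_abs = 1e-10, eps_rel = 1e-10))$z, 6)
#' @export
admm_fit <- function(problem, lambda, control = admm_control(), warm = NULL) {
  fit <- admm_fit_quiet(problem, lambda, control, warm)
  if (!fit$converged)
    warning(sprintf(
      "ADMM did not converge in %d iterations (r = %.2e, s = %.2e)",
      fit$iterations, fit$primal_residual, fit$dual_residual))
  fit
}

# same as admm_fit but leaves non-convergence to the caller (path/benchmarks
# record it per lambda instead of warning repeatedly)
admm_fit_quiet <- function(problem, lambda, control = admm_control(),
                           warm = NULL) {
  stopifnot(inherits(problem, "constrained_lasso_problem"),
            length(lambda) == 1L, lambda >= 0)
  m <- ncol(problem$design)
  rho <- rho_for(control, lambda, problem$design)
  x0 <- z0 <- numeric(m); u1 <- 0; u2 <- numeric(m)
  if (!is.null(warm)) {
    x0 <- warm$x; z0 <- warm$z; u1 <- warm$u1; u2 <- warm$u2
    stopifnot(length(x0) == m, length(z0) == m, length(u2) == m)
    if (!is.null(warm$rho) && warm$rho != rho) { # re-scale y = rho * u
      u1 <- u1 * warm$rho / rho
      u2 <- u2 * warm$rho / rho
    }
  }
  res <- admm_path_cpp(problem$design, problem$response,
                       problem$constraint_row, problem$constraint_value,
                       as.numeric(problem$penalize), lambda,
                       rho, control$eps_abs, control$eps_rel,
                       control$max_iter, x0, z0, u1, u2,
                       problem$constrained)
  sol <- list(x = drop(res$x), z = drop(res$z),
              u1 = res$u1[1L], u2 = drop(res$u2),
              iterations = res$iterations[1L],
              primal_residual = res$primal_residual[1L],
              dual_residual = res$dual_residual[1L],
              converged = res$converged[1L] == 1L,
              lambda = lambda, rho = rho,
              lemma_branch = res$lemma_branch)
  # solution of record: the primal iterate with its (tolerance-level)
  # constraint residual spread over the constrained coefficients, so the
  # equality constraint holds exactly and downstream peeling preconditions
  # are met; for unconstrained problems the sparse split iterate is reported
  if (problem$constrained) {
    cw <- problem$constraint_row
    sol$coefficients <- sol$x +
      cw * (problem$constraint_value - sum(cw * sol$x)) / sum(cw^2)
  } else {
    sol$coefficients <- sol$z
  }
  sol$objective <- lasso_objective(problem, sol$coefficients, lambda)
  structure(sol, class = "admm_solution")
}

#' @export
print.admm_solution <- function(x, ...) {
  cat(sprintf(paste0(
    "ADMM solution at lambda = %.4g: %s in %d iteration(s)\n",
    "  objective %.6g, primal residual %.2e, dual residual %.2e\n"),
    x$lambda, if (x$converged) "converged" else "NOT converged",
    x$iterations, x$objective, x$primal_residual, x$dual_residual))
  invisible(x)
}

#' Unconstrained lasso fit (baseline)
#'
#' Convenience wrapper: solves the same penalized least-squares problem with
#' the equality constraint removed, as used by the pair-design ("Lasso 1")
#' and log-design ("Lasso 2") baselines.
#'
#' @inheritParams admm_fit
#' @return An `admm_solution` (see [admm_fit()]).
#' @export
unconstrained_fit <- function(problem, lambda, control = admm_control(),
                              warm = NULL) {
  stopifnot(inherits(problem, "constrained_lasso_problem"))
  if (problem$constrained) {
    problem$constrained <- FALSE
    problem$constraint_row <- rep(0, ncol(problem$design))
    problem$constraint_value <- 0
  }
  admm_fit(problem, lambda, control, warm)
}

#' Largest penalty level of a regularization path
#'
#' \eqn{\lambda_{\max} = \|A^T b\|_\infty} over penalized columns, at which
#' all penalized coefficients are zero. When the problem has an intercept the
#' response is mean-centered first (the intercept absorbs the mean).
#'
#' @param problem A [constrained_lasso_problem].
#' @return Positive scalar.
#' @export
lambda_max <- function(problem) {
  stopifnot(inherits(problem, "constrained_lasso_problem"))
  b <- problem$response
  if (problem$intercept) b <- b - mean(b)
  A <- problem$design[, problem$penalize, drop = FALSE]
  lmax <- max(abs(crossprod(A, b)))
  if (lmax == 0)
    stop("response is zero (after intercept centering); the path is degenerate")
  lmax
}

#' Geometric penalty grid
#'
#' Decreasing sequence of `count` values from `lmax` down to
#' `eps_lambda * lmax`, uniformly spaced on the log scale.
#'
#' @param lmax Positive largest penalty.
#' @param eps_lambda Ratio of smallest to largest penalty, in (0, 1).
#' @param count Number of grid points (at least 2; default 100).
#' @return Numeric vector of length `count`, strictly decreasing.
#' @examples
#' lambda_grid(100, 0.01, 3) # 100, 10, 1
#' @export
lambda_grid <- function(lmax, eps_lambda = 0.01, count = 100L) {
  stopifnot(lmax > 0, eps_lambda > 0, eps_lambda < 1)
  if (count < 2) stop("'count' must be at least 2")
  exp(seq(log(lmax), log(eps_lambda * lmax), length.out = count))
}

#' Solve a warm-started regularization path
#'
#' Fits the problem at each penalty of a decreasing sequence, initializing
#' every solve from the previous solution. The factorization used by the
#' x-update does not depend on lambda and is computed once for the whole
#' path.
#'
#' @param problem A [constrained_lasso_problem].
#' @param lambdas Decreasing positive sequence; when `NULL`, a
#'   [lambda_grid()] from [lambda_max()] with `nlambda` points and ratio
#'   `lambda_min_ratio` is used.
#' @param control An [admm_control] list.
#' @param nlambda,lambda_min_ratio Grid parameters used when `lambdas` is
#'   `NULL`.
#' @return An object of class `solution_path`: `lambda`, `beta` (coefficient
#'   matrix, predictors x lambdas, from the sparse z iterate), `a0`
#'   (intercepts, zero when the problem has none), `iterations`,
#'   `converged`, `primal_residual`, `dual_residual`, `df` (nonzero counts)
#'   and the `problem` metadata.
#' @export
solve_path <- function(problem, lambdas = NULL, control = admm_control(),
                       nlambda = 100L, lambda_min_ratio = 0.01) {
  stopifnot(inherits(problem, "constrained_lasso_problem"))
  if (is.null(lambdas))
    lambdas <- lambda_grid(lambda_max(problem), lambda_min_ratio, nlambda)
  lambdas <- as.numeric(lambdas)
  if (length(lambdas) > 1L && any(diff(lambdas) >= 0))
    stop("'lambdas' must be strictly decreasing")
  if (any(lambdas < 0)) stop("'lambdas' must be non-negative")
  m <- ncol(problem$design)
  res <- admm_path_cpp(problem$design, problem$response,
                       problem$constraint_row, problem$constraint_value,
                       as.numeric(problem$penalize), lambdas,
                       rho_for(control, lambdas, problem$design),
                       control$eps_abs,
                       control$eps_rel, control$max_iter, numeric(m),
                       numeric(m), 0, numeric(m), problem$constrained)
  Z <- res$z
  if (problem$intercept) {
    a0 <- Z[1L, ]
    beta <- Z[-1L, , drop = FALSE]
  } else {
    a0 <- rep(0, length(lambdas))
    beta <- Z
  }
  rownames(beta) <- problem$varnames
  structure(list(lambda = lambdas, beta = beta, a0 = a0,
                 iterations = as.integer(res$iterations),
                 converged = res$converged == 1L,
                 primal_residual = drop(res$primal_residual),
                 dual_residual = drop(res$dual_residual),
                 df = colSums(beta != 0),
                 intercept = problem$intercept,
                 constrained = problem$constrained,
                 n = nrow(problem$design)),
            class = "solution_path")
}

#' @export
print.solution_path <- function(x, ...) {
  cat(sprintf(
    "Solution path: %d lambda value(s) in [%.4g, %.4g], %d predictor(s)\n",
    length(x$lambda), min(x$lambda), max(x$lambda), nrow(x$beta)))
  cat(sprintf("  converged at %d/%d lambda(s); df range %d..%d\n",
              sum(x$converged), length(x$lambda), min(x$df), max(x$df)))
  invisible(x)
}

#' @export
coef.solution_path <- function(object, ...) {
  rbind(`(Intercept)` = object$a0, object$beta)
}

#' Predict from a solution path
#'
#' @param object A `solution_path`.
#' @param newx Matrix of predictors on the same scale as the training design
#'   (log expressions; without the intercept column).
#' @param ... Unused.
#' @return Matrix of fitted values, samples x lambdas.
#' @export
predict.solution_path <- function(object, newx, ...) {
  newx <- as.matrix(newx)
  stopifnot(ncol(newx) == nrow(object$beta))
  sweep(newx %*% object$beta, 2L, object$a0, `+`)
}

#' Pairwise log-ratio design matrix
#'
#' Expands a samples x genes matrix of log expressions into the
#' \eqn{q = p(p-1)/2} pairwise difference columns
#' \eqn{\log x_j - \log x_k}, ordered lexicographically
#' (1,2), (1,3), ..., (p-1,p).
#'
#' @param log_expr Numeric matrix, samples in rows, genes in columns
#'   (`p >= 2`).
#' @return Numeric matrix with `p*(p-1)/2` columns. The attribute `"pairs"`
#'   stores the (j, k) index pair of every column; column names are
#'   `"<j>/<k>"` built from input column names or indices.
#' @export
build_pair_design <- function(log_expr) {
  log_expr <- as.matrix(log_expr)
  p <- ncol(log_expr)
  if (p < 2) stop("at least two genes are required to form pairs")
  pairs <- utils::combn(p, 2L)
  out <- log_expr[, pairs[1L, ], drop = FALSE] -
    log_expr[, pairs[2L, ], drop = FALSE]
  nms <- colnames(log_expr)
  if (is.null(nms)) nms <- as.character(seq_len(p))
  colnames(out) <- paste0(nms[pairs[1L, ]], "/", nms[pairs[2L, ]])
  attr(out, "pairs") <- t(pairs)
  out
}
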
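#' AR(1) correlation matrix
#'
#' \eqn{V_{ij} = \rho^{|i-j|}}, the correlation structure of the simulated
#' log expressions (default base 0.5). Symmetric positive definite for
#' `|rho| < 1`.
#'
#' @param p Dimension (positive integer).
#' @param rho Correlation base, `|rho| < 1`.
#' @return A `p x p` numeric matrix.
#' @export
ar1_covariance <- function(p, rho = 0.5) {
  p <- as.integer(p)
  stopifnot(p >= 1)
  if (abs(rho) >= 1) stop("'rho' must satisfy |rho| < 1")
  rho^abs(outer(seq_len(p), seq_len(p), `-`))
}

#' Simulation setting for the gene-pair generative model
#'
#' Describes one simulated condition: `p` genes whose log expressions are
#' multivariate normal with AR(1) correlation, a continuous response
#' generated from a sparse gene-pair model with noise standard deviation
#' `sigma`. Three built-in sparse pair structures are provided (all on the
#' first four genes, hence `p >= 4`):
#' \describe{
#'   \item{1}{\eqn{\alpha_{12}=1, \alpha_{13}=0.5, \alpha_{24}=0.5}: not a
#'     minimum-L1 representation (two same-sign pairs meet at gene 2);
#'     induced \eqn{\beta = (1.5, -0.5, -0.5, -0.5, 0, \ldots)}.}
#'   \item{2}{\eqn{\alpha_{12}=1, \alpha_{13}=0.5, \alpha_{24}=-0.5}:
#'     minimum-L1 but not unique (pairs (1,3) and (2,4) are disjoint);
#'     induced \eqn{\beta = (1.5, -1.5, -0.5, 0.5, 0, \ldots)}.}
#'   \item{3}{\eqn{\alpha_{12}=1, \alpha_{13}=0.5, \alpha_{14}=0.5}: the
#'     unique minimum-L1 star on hub gene 1; induced
#'     \eqn{\beta = (2, -1, -0.5, -0.5, 0, \ldots)}.}
#' }
#' A custom [pair_coefficients] object may be supplied instead.
#'
#' @param setting_id 1, 2, 3 or `"custom"`.
#' @param p Gene count (default 20).
#' @param n Training sample size (default 50).
#' @param sigma Noise standard deviation (default 0.5, positive).
#' @param ar_rho AR(1) correlation base (default 0.5).
#' @param alpha A [pair_coefficients] object when `setting_id = "custom"`.
#' @return A list of class `simulation_setting` with the true `alpha`, the
#'   induced `beta`, and the condition parameters.
#' @export
simulation_setting <- function(setting_id, p = 20L, n = 50L, sigma = 0.5,
                               ar_rho = 0.5, alpha = NULL) {
  p <- as.integer(p); n <- as.integer(n)
  stopifnot(sigma > 0, ar_rho >= 0, ar_rho < 1, n >= 1)
  if (identical(setting_id, "custom")) {
    stopifnot(inherits(alpha, "pair_coefficients"), alpha$p == p)
  } else {
    setting_id <- as.integer(setting_id)
    if (!setting_id %in% 1:3)
      stop("'setting_id' must be 1, 2, 3 or \"custom\"")
    if (p < 4) stop("built-in settings place pairs on genes 1..4; need p >= 4")
    val <- switch(setting_id,
                  c(1, 0.5, 0.5),   # (1,2) (1,3) (2,4)
                  c(1, 0.5, -0.5),  # (1,2) (1,3) (2,4)
                  c(1, 0.5, 0.5))   # (1,2) (1,3) (1,4)
    jk <- switch(setting_id,
                 cbind(c(1, 1, 2), c(2, 3, 4)),
                 cbind(c(1, 1, 2), c(2, 3, 4)),
                 cbind(c(1, 1, 1), c(2, 3, 4)))
    alpha <- pair_coefficients(p, jk[, 1L], jk[, 2L], val)
  }
  beta <- beta_from_alpha(alpha)
  stopifnot(abs(sum(beta)) < 1e-12)
  structure(list(setting_id = setting_id, p = p, n = n, sigma = sigma,
                 ar_rho = ar_rho, alpha = alpha, beta = beta),
            class = "simulation_setting")
}

#' @export
print.simulation_setting <- function(x, ...) {
  cat(sprintf(
    "Simulation setting %s: p = %d, n = %d, sigma = %.3g, AR(1) rho = %.3g\n",
    x$setting_id, x$p, x$n, x$sigma, x$ar_rho))
  cat(sprintf("  true pairs: %d; true beta support: %d\n",
              length(x$alpha), sum(x$beta != 0)))
  invisible(x)
}

# n draws from N(0, V) via the Cholesky factor (deterministic given the RNG
# state); V = AR(1) correlation
rmvn_ar1 <- function(n, p, rho) {
  R <- chol(ar1_covariance(p, rho))
  matrix(stats::rnorm(n * p), n, p) %*% R
}

#' Generate a dataset from a simulation setting
#'
#' Draws `n_points` log-expression vectors iid from \eqn{N(0, V)} with AR(1)
#' covariance, then the response \eqn{y = X\beta + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)} iid and independent of the design,
#' where \eqn{\beta} is induced by the setting's true pair coefficients.
#'
#' @param setting A [simulation_setting].
#' @param n_points Number of samples to draw (defaults to `setting$n`).
#' @param seed Integer seed; fully determines the output. The global RNG
#'   state is left untouched.
#' @return A list of class `pz_dataset`: `log_expr` (`n_points x p`),
#'   `response`, `true_alpha`, `true_beta`, `setting`, `seed`.
#' @export
generate_dataset <- function(setting, n_points = setting$n, seed) {
  stopifnot(inherits(setting, "simulation_setting"), n_points >= 1)
  withr::with_seed(as.integer(seed), {
    X <- rmvn_ar1(n_points, setting$p, setting$ar_rho)
    eps <- stats::rnorm(n_points, sd = setting$sigma)
  })
  y <- drop(X %*% setting$beta) + eps
  structure(list(log_expr = X, response = y,
                 true_alpha = setting$alpha, true_beta = setting$beta,
                 setting = setting, seed = as.integer(seed)),
            class = "pz_dataset")
}

#' Generate a dense centered-coefficient benchmark problem
#'
#' The convergence benchmark draws the true gene-level coefficients
#' \eqn{\beta_j} iid from \eqn{N(0,1)} and centers them to sum to zero, with
#' the same AR(1) design and unit-variance noise. The corresponding
#' minimum-L1 pair representation is obtained by [peel()].
#'
#' @param p Gene count (`p >= 2`).
#' @param n Sample size.
#' @param seed Integer seed; fully determines the output.
#' @param ar_rho AR(1) correlation base (default 0.5).
#' @return A `pz_dataset` (see [generate_dataset()]); `setting` is the
#'   equivalent `"custom"` [simulation_setting] with `sigma = 1`.
#' @export
generate_dense_beta_dataset <- function(p, n, seed, ar_rho = 0.5) {
  p <- as.integer(p); n <- as.integer(n)
  stopifnot(p >= 2, n >= 1)
  withr::with_seed(as.integer(seed), {
    beta <- stats::rnorm(p)
    beta <- beta - mean(beta)
    X <- rmvn_ar1(n, p, ar_rho)
    eps <- stats::rnorm(n)
  })
  alpha <- peel(beta)$alpha
  setting <- simulation_setting("custom", p = p, n = n, sigma = 1,
                                ar_rho = ar_rho, alpha = alpha)
  # the peeled representation reproduces the centered draw exactly
  setting$beta <- beta
  y <- drop(X %*% beta) + eps
  structure(list(log_expr = X, response = y,
                 true_alpha = alpha, true_beta = beta,
                 setting = setting, seed = as.integer(seed)),
            class = "pz_dataset")
}

#' @export
print.pz_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %d sample(s) x %d gene(s), seed %d\n",
              nrow(x$log_expr), ncol(x$log_expr), x$seed))
  invisible(x)
}

#' Add random per-sample shifts to a log-expression matrix
#'
#' Adds an iid \eqn{N(0,1)} constant to every row (sample), emulating
#' residual per-sample normalization differences: a per-sample rescaling of
#' raw expression is a per-sample additive shift in log space. Predictions
#' of any sum-to-zero model are unchanged by such shifts.
#'
#' @param log_expr Numeric matrix, samples in rows.
#' @param seed Integer seed for the shifts.
#' @return The shifted matrix, with the shift vector in attribute
#'   `"shifts"`.
#' @export
apply_sample_shifts <- function(log_expr, seed) {
  log_expr <- as.matrix(log_expr)
  shifts <- withr::with_seed(as.integer(seed),
                             stats::rnorm(nrow(log_expr)))
  structure(log_expr + shifts, shifts = shifts)
}

#' Randomly rescale a raw expression matrix
#'
#' Multiplies a strictly positive genes x samples expression matrix by
#' random positive per-gene (row) and/or per-sample (column) factors,
#' emulating gene-length and library-size/sequencing-depth normalization
#' changes. Factors are log-normal(0, 1); any positive law preserves the
#' invariance this transformation is used to probe. On the log scale the
#' result differs from the input by rank-1 row/column offsets, which
#' sum-to-zero fits (per-sample) and intercepts (per-gene) absorb.
#'
#' @param expression Strictly positive numeric matrix, genes x samples.
#' @param per_gene Apply per-gene (row) factors? Default `TRUE`.
#' @param per_sample Apply per-sample (column) factors? Default `TRUE`.
#' @param seed Integer seed for the factors.
#' @return The rescaled matrix with attributes `"gene_factors"` and
#'   `"sample_factors"` (all-ones when the corresponding flag is off).
#' @export
apply_random_scaling <- function(expression, per_gene = TRUE,
                                 per_sample = TRUE, seed) {
  expression <- as.matrix(expression)
  if (any(expression <= 0))
    stop("'expression' must be strictly positive to be rescaled and logged")
  ng <- nrow(expression); ns <- ncol(expression)
  withr::with_seed(as.integer(seed), {
    gf <- if (per_gene) exp(stats::rnorm(ng)) else rep(1, ng)
    sf <- if (per_sample) exp(stats::rnorm(ns)) else rep(1, ns)
  })
  out <- expression * gf # row factors recycle down columns
  out <- sweep(out, 2L, sf, `*`)
  structure(out, gene_factors = gf, sample_factors = sf)
}
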
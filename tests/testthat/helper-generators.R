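# shared generators and independent oracles for the test suite

# random sparse pair-coefficient set on p genes
random_alpha <- function(p = sample(4:12, 1), n_pairs = NULL) {
  q <- p * (p - 1) / 2
  if (is.null(n_pairs)) n_pairs <- sample.int(min(q, 6L), 1)
  pairs <- utils::combn(p, 2)[, sample.int(q, n_pairs), drop = FALSE]
  pair_coefficients(p, pairs[1, ], pairs[2, ], stats::rnorm(n_pairs))
}

# random centered (sum-to-zero) gene-level coefficient vector
random_centered_beta <- function(p = sample(2:30, 1)) {
  b <- stats::rnorm(p)
  b - mean(b)
}

# dense antisymmetric matrix view of a pair_coefficients object
alpha_as_matrix <- function(alpha) {
  M <- matrix(0, alpha$p, alpha$p)
  for (i in seq_along(alpha$value)) {
    M[alpha$j[i], alpha$k[i]] <- alpha$value[i]
    M[alpha$k[i], alpha$j[i]] <- -alpha$value[i]
  }
  M
}

matrix_as_alpha <- function(M) {
  p <- nrow(M)
  ut <- which(upper.tri(M) & M != 0, arr.ind = TRUE)
  pair_coefficients(p, ut[, 1], ut[, 2], M[ut])
}

# brute-force beta from the antisymmetric matrix (independent of the
# sparse implementation): beta_j = sum_k alpha_{jk}
beta_by_rowsum <- function(alpha) rowSums(alpha_as_matrix(alpha))

# minimum L1 norm over all pair representations of beta, via an
# independent linear program (split variables, incidence constraints)
min_l1_by_lp <- function(beta) {
  p <- length(beta)
  pairs <- utils::combn(p, 2)
  q <- ncol(pairs)
  M <- matrix(0, p, q)
  for (c in seq_len(q)) {
    M[pairs[1, c], c] <- 1
    M[pairs[2, c], c] <- -1
  }
  A3 <- cbind(M, -M)
  b3 <- beta
  flip <- b3 < 0 # simplex() wants non-negative right-hand sides
  A3[flip, ] <- -A3[flip, , drop = FALSE]
  b3[flip] <- -b3[flip]
  drop_row <- which.min(abs(b3)) # rows sum to zero; one is redundant
  sol <- boot::simplex(a = rep(1, 2 * q),
                       A3 = A3[-drop_row, , drop = FALSE],
                       b3 = b3[-drop_row], maxi = FALSE)
  stopifnot(sol$solved == 1)
  unname(sol$value)
}

# small random regression problem for solver tests
random_problem <- function(p, n, constrained = TRUE, intercept = FALSE) {
  X <- matrix(stats::rnorm(n * p), n, p)
  y <- stats::rnorm(n)
  constrained_lasso_problem(X, y, intercept = intercept,
                            constrained = constrained)
}
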
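#' Project a coefficient vector onto the sum-to-zero constraint
#'
#' Subtracts the mean so the result sums to zero up to machine rounding.
#' Used as numerical hygiene before peeling a fitted coefficient vector whose
#' constraint residual is at solver-tolerance level.
#'
#' @param beta Finite numeric vector.
#' @return `beta - mean(beta)`.
#' @examples
#' project_sum_zero(c(1, 2, 3)) # (-1, 0, 1)
#' @export
project_sum_zero <- function(beta) {
  beta <- as.numeric(beta)
  if (!length(beta) || any(!is.finite(beta)))
    stop("'beta' must be a non-empty finite numeric vector")
  beta - mean(beta)
}

#' One peeling iteration
#'
#' Performs a single iteration of the peeling recursion on the current
#' working vector: select the most positive entry `k1` and the most negative
#' entry `k2` (lowest index on ties), assign the pair weight
#' `min(beta[k1], -beta[k2])`, and subtract it from both sides so that at
#' least one of the two entries becomes exactly zero. Unlike [peel()], the
#' input need not sum to zero — this is the elementary move applied to the
#' working vector between iterations.
#'
#' @param beta Finite numeric working vector.
#' @param dust Entries with magnitude at or below `dust` are treated as
#'   exhausted (default `1e-12`).
#' @return `NULL` when no strictly positive and strictly negative entries
#'   remain; otherwise a list with `k1`, `k2`, `weight` and the updated
#'   vector `beta`.
#' @examples
#' peel_step(c(1.5, -0.5)) # weight 0.5, beta becomes (1, 0)
#' @export
peel_step <- function(beta, dust = 1e-12) {
  beta <- as.numeric(beta)
  if (!length(beta) || any(!is.finite(beta))) stop("'beta' must be finite")
  hi <- which.max(beta); lo <- which.min(beta) # which.* take the lowest index
  if (beta[hi] <= dust || beta[lo] >= -dust) return(NULL)
  wt <- min(beta[hi], -beta[lo])
  beta[hi] <- beta[hi] - wt # exact zero when wt == beta[hi]
  beta[lo] <- beta[lo] + wt
  list(k1 = hi, k2 = lo, weight = wt, beta = beta)
}

#' Peel a sum-to-zero coefficient vector into minimum-L1 gene pairs
#'
#' Converts a gene-level coefficient vector \eqn{\beta} with
#' \eqn{\sum_j \beta_j = 0} into an equivalent sparse set of gene-pair
#' coefficients \eqn{\hat\alpha} of minimum L1 norm. Each iteration selects
#' the most positive and most negative remaining entries (ties broken by
#' lowest index), transfers the smaller magnitude onto that pair, and zeroes
#' one of the two entries; the number of nonzeros strictly decreases, so at
#' most `length(beta)` iterations are needed. The result reproduces `beta`
#' exactly under [beta_from_alpha()], satisfies
#' \eqn{\|\hat\alpha\|_1 = \|\beta\|_1/2} (the minimum possible), passes
#' [is_min_l1_pairs()], and stores at most `length(beta) - 1` pairs.
#'
#' The minimum-L1 representation need not be unique (see
#' [is_unique_min_l1()]); different tie-breaking orders can give different
#' pair sets of identical L1 norm. The most-positive/most-negative,
#' lowest-index rule makes this implementation deterministic.
#'
#' @param beta Numeric vector summing to zero within `tol` (it is
#'   mean-projected before peeling so the recursion terminates cleanly).
#' @param tol Tolerance for the sum-to-zero precondition; default
#'   `1e-8 * max(1, sum(abs(beta)))`.
#' @param dust Pair weights below this value, arising from floating-point
#'   residue near termination, are dropped (default `1e-12`).
#' @param gene_ids Optional identifiers forwarded to the result.
#' @return A list with elements
#'   \describe{
#'     \item{alpha}{[pair_coefficients] with the peeled pairs.}
#'     \item{trace}{data frame of peeling steps (`k1`, `k2`, `weight`).}
#'     \item{iterations}{Number of peeling iterations.}
#'   }
#' @examples
#' pe <- peel(c(3, -5, 2))
#' as.data.frame(pe$alpha) # pairs (1,2): 3 and (2,3): -2
#' @export
peel <- function(beta, tol = NULL, dust = 1e-12, gene_ids = NULL) {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta))) stop("'beta' must be finite")
  p <- length(beta)
  if (is.null(tol)) tol <- 1e-8 * max(1, sum(abs(beta)))
  if (abs(sum(beta)) > tol)
    stop(sprintf(
      "sum(beta) = %.3g exceeds the sum-to-zero tolerance %.3g; %s",
      sum(beta), tol, "peeling requires a sum-to-zero input"))
  bt <- project_sum_zero(beta)
  if (p == 1L) bt <- 0 # a single coefficient can only be zero

  k1s <- integer(); k2s <- integer(); w <- numeric()
  iter <- 0L
  repeat {
    st <- peel_step(bt, dust = dust)
    if (is.null(st)) break
    if (iter >= p) stop("peeling failed to terminate in p iterations")
    iter <- iter + 1L
    nz_before <- sum(bt != 0)
    bt <- st$beta
    stopifnot(sum(bt != 0) < nz_before)
    k1s[iter] <- st$k1; k2s[iter] <- st$k2; w[iter] <- st$weight
  }

  keep <- w > dust
  k1s <- k1s[keep]; k2s <- k2s[keep]; w <- w[keep]
  sw <- k1s > k2s
  alpha <- pair_coefficients(
    p,
    j = ifelse(sw, k2s, k1s),
    k = ifelse(sw, k1s, k2s),
    value = ifelse(sw, -w, w),
    gene_ids = gene_ids
  )
  list(alpha = alpha,
       trace = data.frame(step = seq_along(w), k1 = k1s, k2 = k2s, weight = w),
       iterations = iter)
}
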
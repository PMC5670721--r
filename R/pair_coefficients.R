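#' Sparse gene-pair coefficients
#'
#' A `pair_coefficients` object stores the coefficients of a gene-pair
#' (log-ratio) regression model: a sparse, antisymmetric set of weights
#' \eqn{\alpha_{jk}} on the predictors \eqn{\log(x_j/x_k)}, \eqn{1 \le j < k
#' \le p}. Only the upper-triangular entries (\eqn{j < k}) are stored; by
#' convention \eqn{\alpha_{kj} = -\alpha_{jk}}. Entries that are exactly zero
#' are dropped so the representation is canonical.
#'
#' @param p Number of genes (positive integer).
#' @param j,k Integer vectors of gene indices with `j < k`, both in `1:p`.
#' @param value Numeric vector of pair coefficients, same length as `j`.
#' @param gene_ids Optional character vector of `p` gene identifiers used
#'   when printing or serializing; indices remain the internal currency.
#'
#' @return An object of class `pair_coefficients`: a list with elements
#'   `p`, `j`, `k`, `value` and optionally `gene_ids`.
#' @examples
#' a <- pair_coefficients(3, j = c(1, 2), k = c(2, 3), value = c(3, -2))
#' beta_from_alpha(a) # (3, -5, 2)
#' @export
pair_coefficients <- function(p, j = integer(), k = integer(),
                              value = numeric(), gene_ids = NULL) {
  p <- as.integer(p)
  stopifnot(length(p) == 1L, p >= 1L)
  j <- as.integer(j); k <- as.integer(k); value <- as.numeric(value)
  if (length(j) != length(k) || length(j) != length(value))
    stop("'j', 'k' and 'value' must have equal length")
  if (any(!is.finite(value)))
    stop("pair coefficients must be finite")
  if (length(j)) {
    if (any(j < 1L) || any(k > p)) stop("pair indices must lie in [1, p]")
    if (any(j >= k)) stop("pair indices must satisfy j < k")
    if (anyDuplicated(paste(j, k))) stop("duplicate pair indices")
  }
  keep <- value != 0
  j <- j[keep]; k <- k[keep]; value <- value[keep]
  ord <- order(j, k)
  out <- list(p = p, j = j[ord], k = k[ord], value = value[ord])
  if (!is.null(gene_ids)) {
    if (length(gene_ids) != p || anyDuplicated(gene_ids))
      stop("'gene_ids' must be ", p, " unique identifiers")
    out$gene_ids <- as.character(gene_ids)
  }
  structure(out, class = "pair_coefficients")
}

#' @export
print.pair_coefficients <- function(x, ...) {
  cat(sprintf("Gene-pair coefficients: %d gene(s), %d stored pair(s)\n",
              x$p, length(x$value)))
  if (length(x$value)) {
    df <- as.data.frame(x)
    print(utils::head(df, 10L), row.names = FALSE)
    if (nrow(df) > 10L) cat("... and", nrow(df) - 10L, "more\n")
  }
  invisible(x)
}

#' @export
as.data.frame.pair_coefficients <- function(x, ...) {
  ids <- x$gene_ids
  if (is.null(ids)) {
    data.frame(gene_j = x$j, gene_k = x$k, alpha = x$value)
  } else {
    data.frame(gene_j = ids[x$j], gene_k = ids[x$k], alpha = x$value,
               stringsAsFactors = FALSE)
  }
}

#' @export
length.pair_coefficients <- function(x) length(x$value)

l1_norm <- function(v) sum(abs(v))

#' Gene-level coefficients induced by pair coefficients
#'
#' Collapses a gene-pair coefficient set \eqn{\alpha} to the equivalent
#' gene-level coefficient vector \eqn{\beta} of the sum-to-zero model:
#' \eqn{\beta_j = \sum_{k \ne j} \alpha_{jk}} (using the antisymmetric
#' extension \eqn{\alpha_{kj} = -\alpha_{jk}}). The result always satisfies
#' \eqn{\sum_j \beta_j = 0} up to floating-point rounding, so both
#' parameterizations give the same linear predictor on log expressions.
#'
#' @param alpha A [pair_coefficients] object.
#' @return Numeric vector of length `alpha$p` summing to zero.
#' @examples
#' beta_from_alpha(pair_coefficients(3, c(1, 2), c(2, 3), c(3, -2)))
#' @export
beta_from_alpha <- function(alpha) {
  stopifnot(inherits(alpha, "pair_coefficients"))
  beta <- numeric(alpha$p)
  if (length(alpha$value)) {
    add <- tapply(alpha$value, alpha$j, sum)
    sub <- tapply(alpha$value, alpha$k, sum)
    beta[as.integer(names(add))] <- beta[as.integer(names(add))] + add
    beta[as.integer(names(sub))] <- beta[as.integer(names(sub))] - sub
  }
  if (!is.null(alpha$gene_ids)) names(beta) <- alpha$gene_ids
  beta
}

#' Is a pair representation of minimum L1 norm?
#'
#' Many pair-coefficient sets \eqn{\alpha} induce the same gene-level
#' \eqn{\beta}: adding a constant along any cycle of indices leaves the model
#' unchanged. Among them the "simplest" representations are those of minimum
#' L1 norm. A representation attains the minimum if and only if no two
#' coefficients sharing an index reinforce each other: \eqn{\alpha_{ij}
#' \alpha_{jk} \le 0} for all \eqn{i \ne j}, \eqn{j \ne k} (antisymmetric
#' extension), equivalently \eqn{\|\alpha\|_1 = \|\beta\|_1 / 2}.
#'
#' The check runs over stored nonzeros grouped by incident gene, so it costs
#' O(A) for A stored pairs rather than O(p^3).
#'
#' @param alpha A [pair_coefficients] object.
#' @return `TRUE` or `FALSE`. When `FALSE`, the attribute `"violation"`
#'   holds the first violating index triple `(i, j, k)` (middle index `j`
#'   scanned in increasing order) with
#'   \eqn{\alpha_{ij}\alpha_{jk} > 0}.
#' @examples
#' is_min_l1_pairs(pair_coefficients(4, c(1, 1, 2), c(2, 3, 4), c(1, 0.5, 0.5)))
#' @export
is_min_l1_pairs <- function(alpha) {
  stopifnot(inherits(alpha, "pair_coefficients"))
  if (!length(alpha$value)) return(TRUE)
  # outgoing coefficients per vertex: alpha_{v,w} for stored (j,k):
  #   vertex j sees +value toward k, vertex k sees -value toward j
  vert <- c(alpha$j, alpha$k)
  nb   <- c(alpha$k, alpha$j)
  outc <- c(alpha$value, -alpha$value)
  for (v in sort(unique(vert))) {
    idx <- which(vert == v)
    pos <- idx[outc[idx] > 0]
    neg <- idx[outc[idx] < 0]
    if (length(pos) && length(neg)) {
      # alpha_{iv} > 0 (i.e. outgoing alpha_{v,i} < 0) and alpha_{v,k} > 0
      i <- min(nb[neg]); k <- min(nb[pos])
      return(structure(FALSE, violation = c(i = i, j = v, k = k)))
    }
  }
  TRUE
}

#' Is a pair representation the unique minimum-L1 one?
#'
#' The minimum-L1 representation of a gene-level coefficient vector is unique
#' exactly when it is a "star": it satisfies the minimum-L1 condition of
#' [is_min_l1_pairs()] and all nonzero pairs share one common hub gene.
#' Equivalently, the induced \eqn{\beta} has a hub index \eqn{j} with
#' \eqn{|\beta_j| = \sum_{i \ne j} |\beta_i|}.
#'
#' @param alpha A [pair_coefficients] object.
#' @return `TRUE` or `FALSE`. When `TRUE` and pairs exist, the attribute
#'   `"hub"` holds the common gene index.
#' @export
is_unique_min_l1 <- function(alpha) {
  stopifnot(inherits(alpha, "pair_coefficients"))
  if (!length(alpha$value)) return(TRUE)
  if (!isTRUE(c(is_min_l1_pairs(alpha)))) return(FALSE)
  common <- Reduce(intersect, Map(c, alpha$j, alpha$k))
  if (!length(common)) return(FALSE)
  hub <- min(common)
  structure(TRUE, hub = hub)
}

#' Support counts of a pair representation and its induced gene vector
#'
#' Counts the nonzero pair coefficients (`A`) and nonzero induced gene-level
#' coefficients (`B`), using a magnitude threshold suited to fitted
#' (floating-point) coefficients, and evaluates the structural conditions for
#' minimum-L1 and unique representations. The counts always satisfy
#' \eqn{B \le 2A}; a minimum-L1 representation additionally satisfies
#' \eqn{2\sqrt{A} \le B} (its incidence graph is bipartite), and a unique
#' (star) representation with `A > 0` has \eqn{B = A + 1}.
#'
#' @param alpha A [pair_coefficients] object.
#' @param nonzero_tol Magnitudes at or below this threshold count as zero
#'   (default `1e-10`, matching the solver's coefficient dust level).
#' @return A list of class `pair_support_summary` with elements `A`, `B`,
#'   `min_l1`, `unique_min_l1`, `l1_alpha`, `l1_beta`, `nonzero_tol`.
#' @export
pair_support_summary <- function(alpha, nonzero_tol = 1e-10) {
  stopifnot(inherits(alpha, "pair_coefficients"), nonzero_tol >= 0)
  keep <- abs(alpha$value) > nonzero_tol
  a <- pair_coefficients(alpha$p, alpha$j[keep], alpha$k[keep],
                         alpha$value[keep], gene_ids = alpha$gene_ids)
  beta <- beta_from_alpha(a)
  structure(list(
    A = length(a$value),
    B = sum(abs(beta) > nonzero_tol),
    min_l1 = isTRUE(c(is_min_l1_pairs(a))),
    unique_min_l1 = isTRUE(c(is_unique_min_l1(a))),
    l1_alpha = l1_norm(a$value),
    l1_beta = l1_norm(beta),
    nonzero_tol = nonzero_tol
  ), class = "pair_support_summary")
}

#' @export
print.pair_support_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "Pair support: A = %d pair(s), B = %d gene(s)\n",
    "  minimum-L1: %s; unique (star): %s\n",
    "  ||alpha||_1 = %.6g, ||beta||_1 = %.6g\n"),
    x$A, x$B, x$min_l1, x$unique_min_l1, x$l1_alpha, x$l1_beta))
  invisible(x)
}

#' Write or read a pair-coefficient table
#'
#' Pairs are serialized as three-column delimited text (`gene_j`, `gene_k`,
#' `alpha`), one row per stored pair with `j < k`.
#'
#' @param alpha A [pair_coefficients] object.
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns a
#'   [pair_coefficients] object (`gene_ids` must be supplied to map
#'   identifiers back to indices, or the file must contain integer indices
#'   and `p` be given).
#' @export
write_pairs <- function(alpha, path, sep = "\t") {
  stopifnot(inherits(alpha, "pair_coefficients"))
  utils::write.table(as.data.frame(alpha), path, sep = sep,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pairs
#' @param p Gene count (when the file stores integer indices).
#' @param gene_ids Identifier vector defining the index order (when the file
#'   stores identifiers).
#' @export
read_pairs <- function(path, p = NULL, gene_ids = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (!all(c("gene_j", "gene_k", "alpha") %in% names(df)))
    stop("pair table must have columns gene_j, gene_k, alpha")
  if (!is.null(gene_ids)) {
    j <- match(df$gene_j, gene_ids); k <- match(df$gene_k, gene_ids)
    if (anyNA(j) || anyNA(k)) stop("pair table names not all in 'gene_ids'")
    p <- length(gene_ids)
  } else {
    if (is.null(p)) stop("supply 'p' (or 'gene_ids') to read a pair table")
    j <- as.integer(df$gene_j); k <- as.integer(df$gene_k)
  }
  sw <- j > k # tolerate rows stored in either order
  jj <- ifelse(sw, k, j); kk <- ifelse(sw, j, k)
  val <- ifelse(sw, -df$alpha, df$alpha)
  pair_coefficients(p, jj, kk, val, gene_ids = gene_ids)
}
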
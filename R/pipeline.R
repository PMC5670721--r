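#' Read or write a gene expression matrix
#'
#' Expression matrices are delimited text with genes as rows: the first
#' column holds unique gene identifiers, the header row holds unique sample
#' identifiers, and the body holds non-negative normalized expression values
#' (e.g. RSEM estimates). The round trip `write_expression()` then
#' `read_expression()` preserves values to full precision and identifier
#' order.
#'
#' @param path File path.
#' @param sep Field separator (default tab).
#' @return `read_expression` returns a numeric matrix with gene identifiers
#'   as row names and sample identifiers as column names;
#'   `write_expression` returns `path` invisibly.
#' @export
read_expression <- function(path, sep = "\t") {
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, fill = FALSE)
  if (ncol(dt) < 2L) stop("expression file needs id column plus >= 1 sample")
  ids <- as.character(dt[[1L]])
  dup <- which(duplicated(ids))
  if (length(dup))
    stop("duplicate gene identifier '", ids[dup[1L]], "' at line ",
         dup[1L] + 1L)
  vals <- dt[, -1L, drop = FALSE]
  # an all-missing column parses as logical; coerce so it errors as missing
  allna <- vapply(vals, function(col) is.logical(col) && all(is.na(col)),
                  logical(1L))
  vals[allna] <- lapply(vals[allna], as.numeric)
  notnum <- which(!vapply(vals, is.numeric, logical(1L)))
  if (length(notnum))
    stop("column '", names(vals)[notnum[1L]], "' is not numeric")
  mat <- as.matrix(vals)
  if (anyNA(mat)) {
    bad <- which(rowSums(is.na(mat)) > 0)[1L]
    stop("missing value at line ", bad + 1L)
  }
  neg <- which(rowSums(mat < 0) > 0)
  if (length(neg))
    stop("negative expression value at line ", neg[1L] + 1L)
  if (anyDuplicated(colnames(mat))) stop("duplicate sample identifiers")
  rownames(mat) <- ids
  mat
}

#' @rdname read_expression
#' @param expression Numeric matrix, genes x samples, with row and column
#'   names.
#' @export
write_expression <- function(expression, path, sep = "\t") {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("'expression' must have gene row names and sample column names")
  df <- data.frame(gene = rownames(expression), expression,
                   check.names = FALSE)
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Drop genes with low average expression
#'
#' Removes genes whose mean normalized expression across samples is strictly
#' lower than `min_mean` (default 10), the pre-filter applied before
#' correlation screening.
#'
#' @param expression Numeric matrix, genes x samples.
#' @param min_mean Minimum retained row mean (default 10).
#' @return A list with `expression` (retained rows) and `dropped_genes`
#'   (character vector, or row indices when unnamed).
#' @export
filter_low_expression <- function(expression, min_mean = 10) {
  expression <- as.matrix(expression)
  keep <- rowMeans(expression) >= min_mean
  if (!any(keep)) stop("all genes fall below the mean-expression threshold")
  dropped <- if (is.null(rownames(expression))) which(!keep)
             else rownames(expression)[!keep]
  list(expression = expression[keep, , drop = FALSE],
       dropped_genes = dropped)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment (a thin validated wrapper around
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values Numeric vector in \[0, 1\] (NA allowed).
#' @return Adjusted values, monotone in the input order statistics, capped
#'   at 1.
#' @export
bh_adjust <- function(p_values) {
  pv <- p_values[!is.na(p_values)]
  if (length(pv) && (any(pv < 0) || any(pv > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Pearson correlation screen on the log scale
#'
#' For each gene, computes the Pearson correlation between log-transformed
#' expression and the log-transformed response, the two-sided p-value from
#' the t transform with `n - 2` degrees of freedom, and Benjamini-Hochberg
#' adjusted values across all tested genes. A gene is retained when its
#' adjusted value is at most `fdr_cutoff`. Genes with zero variance on the
#' log scale cannot be tested; they are excluded with a recorded reason.
#'
#' @param expression Strictly positive numeric matrix, genes x samples (use
#'   `pseudocount` if zeros are present).
#' @param response Strictly positive numeric vector, one value per sample
#'   (`n >= 3`).
#' @param fdr_cutoff Retention threshold on the adjusted values (default
#'   0.01).
#' @param pseudocount Optional positive constant added to `expression`
#'   before the log transform; `NULL` (default) means zeros are an error.
#' @return A data frame of class `screening_report` with one row per gene:
#'   `gene`, `mean_expression`, `pearson_r`, `p_value`, `fdr`, `retained`,
#'   `reason` (NA or `"zero variance"`).
#' @export
pearson_screen <- function(expression, response, fdr_cutoff = 0.01,
                           pseudocount = NULL) {
  expression <- as.matrix(expression)
  response <- as.numeric(response)
  if (ncol(expression) != length(response))
    stop("ncol(expression) must equal length(response)")
  n <- length(response)
  if (n < 3) stop("at least 3 samples are required for a correlation test")
  if (any(response <= 0)) stop("'response' must be strictly positive")
  if (!is.null(pseudocount)) {
    stopifnot(pseudocount > 0)
    expression <- expression + pseudocount
  }
  if (any(expression <= 0))
    stop("expression has non-positive values; supply 'pseudocount' to ",
         "offset zeros before the log transform")
  lx <- log(expression)
  ly <- log(response)
  lyc <- ly - mean(ly)
  xc <- lx - rowMeans(lx)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(lyc^2))
  r <- drop(xc %*% lyc) / (sx * sy)
  r[sx == 0] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  fdr <- bh_adjust(pval)
  genes <- rownames(expression)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expression)))
  out <- data.frame(
    gene = genes,
    mean_expression = rowMeans(expression),
    pearson_r = r, p_value = pval, fdr = fdr,
    retained = !is.na(fdr) & fdr <= fdr_cutoff,
    reason = ifelse(is.na(r), "zero variance", NA_character_),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("screening_report", "data.frame")
  attr(out, "fdr_cutoff") <- fdr_cutoff
  out
}

#' Fit the gene-pair model on a screened expression matrix
#'
#' End-to-end model fitting on real (or realistic) expression data: log
#' transform, within-sample centering (the centered log-ratio transform,
#' which is model-equivalent under the sum-to-zero constraint), constrained
#' path fit with an unpenalized intercept, minimum-L1 peeling of every
#' solution on the path, and an entry report listing genes in the order
#' they first enter the model as the penalty decreases. The centering makes
#' the whole path — including the data-driven penalty grid, the selected
#' pairs and their entry order — invariant to per-sample rescaling of the
#' raw expression values.
#'
#' @param expression Strictly positive numeric matrix, genes x samples,
#'   typically the retained rows after [filter_low_expression()] and
#'   [pearson_screen()].
#' @param response Numeric response, one value per sample. With
#'   `log_response = TRUE` (default) it must be strictly positive and is
#'   log-transformed to match the correlation screen.
#' @param log_response Log-transform the response? Default `TRUE`.
#' @param pseudocount Optional positive offset added to `expression` before
#'   the log transform (zeros are an error without it).
#' @param lambdas,nlambda,lambda_min_ratio Path grid (see [solve_path()]).
#' @param control An [admm_control] list.
#' @param nonzero_tol Coefficient magnitudes at or below this value count as
#'   zero in entry/peeling reports (default `1e-10`).
#' @return A list of class `pairzero_fit`:
#'   \describe{
#'     \item{path}{the [solve_path()] result (gene rows named).}
#'     \item{pairs}{per-lambda list of peeled [pair_coefficients].}
#'     \item{entry}{data frame of genes ordered by first entry (`gene`,
#'       `lambda_entry`, `entry_order`).}
#'     \item{first_pair}{the pair(s) present at the largest lambda where any
#'       gene is active (NULL when the path never activates).}
#'   }
#' @export
fit_pipeline <- function(expression, response, log_response = TRUE,
                         pseudocount = NULL, lambdas = NULL, nlambda = 100L,
                         lambda_min_ratio = 0.01, control = admm_control(),
                         nonzero_tol = 1e-10) {
  expression <- as.matrix(expression)
  if (ncol(expression) != length(response))
    stop("ncol(expression) must equal length(response)")
  if (!is.null(pseudocount)) {
    stopifnot(pseudocount > 0)
    expression <- expression + pseudocount
  }
  if (any(expression <= 0))
    stop("expression has non-positive values; supply 'pseudocount' to ",
         "offset zeros before the log transform")
  y <- as.numeric(response)
  if (log_response) {
    if (any(y <= 0)) stop("'response' must be positive for log_response")
    y <- log(y)
  }
  genes <- rownames(expression)
  if (is.null(genes)) genes <- as.character(seq_len(nrow(expression)))
  X <- t(log(expression)) # samples x genes
  # center each sample's log expressions (the centered log-ratio transform):
  # model-equivalent under the sum-to-zero constraint, and it makes every
  # downstream quantity — including the data-driven penalty grid — exactly
  # invariant to per-sample rescaling of the raw expression
  X <- X - rowMeans(X)
  colnames(X) <- genes
  prob <- constrained_lasso_problem(X, y, intercept = TRUE)
  path <- solve_path(prob, lambdas = lambdas, control = control,
                     nlambda = nlambda, lambda_min_ratio = lambda_min_ratio)

  active <- abs(path$beta) > nonzero_tol
  pairs <- lapply(seq_along(path$lambda), function(l) {
    bz <- path$beta[, l]
    bz[!active[, l]] <- 0
    if (!any(bz != 0)) {
      pair_coefficients(length(bz), gene_ids = genes)
    } else {
      peel(project_sum_zero(bz), gene_ids = genes)$alpha
    }
  })

  first_idx <- apply(active, 1L, function(a) if (any(a)) which(a)[1L] else NA)
  ord <- order(first_idx, seq_along(first_idx), na.last = TRUE)
  entered <- ord[!is.na(first_idx[ord])]
  entry <- data.frame(gene = genes[entered],
                      lambda_entry = path$lambda[first_idx[entered]],
                      entry_order = seq_along(entered),
                      stringsAsFactors = FALSE)
  l1 <- if (any(active)) min(which(colSums(active) > 0)) else NA_integer_
  structure(list(path = path, pairs = pairs, entry = entry,
                 first_pair = if (is.na(l1)) NULL else pairs[[l1]],
                 genes = genes, nonzero_tol = nonzero_tol),
            class = "pairzero_fit")
}

#' @export
print.pairzero_fit <- function(x, ...) {
  cat(sprintf("Gene-pair fit: %d gene(s), %d lambda value(s)\n",
              length(x$genes), length(x$path$lambda)))
  if (nrow(x$entry)) {
    cat("First genes entering the model:\n")
    print(utils::head(x$entry, 8L), row.names = FALSE)
  } else cat("No gene enters the model on this path\n")
  invisible(x)
}
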
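test_that("pair coefficients collapse to hand-computed gene coefficients", {
  a <- pair_coefficients(3, c(1, 2), c(2, 3), c(3, -2))
  expect_equal(beta_from_alpha(a), c(3, -5, 2))

  expect_equal(beta_from_alpha(pair_coefficients(4)), rep(0, 4))

  a3 <- pair_coefficients(5, c(1, 1, 1), c(2, 3, 4), c(1, 0.5, 0.5))
  expect_equal(beta_from_alpha(a3), c(2, -1, -0.5, -0.5, 0))
})

test_that("constructor enforces the canonical sparse form", {
  expect_error(pair_coefficients(3, 2, 2, 1), "j < k")
  expect_error(pair_coefficients(3, 1, 4, 1), "\\[1, p\\]")
  expect_error(pair_coefficients(4, c(1, 1), c(2, 2), c(1, 2)), "duplicate")
  expect_error(pair_coefficients(3, 1, 2, NaN), "finite")
  # exact zeros are pruned; entries come back sorted
  a <- pair_coefficients(5, c(3, 1, 2), c(4, 2, 3), c(0, 2, 1))
  expect_equal(length(a), 2L)
  expect_equal(a$j, c(1L, 2L))
  expect_equal(as.data.frame(a)$alpha, c(2, 1))
})

test_that("minimum-L1 condition detects same-sign pairs meeting at a gene", {
  s1 <- pair_coefficients(4, c(1, 1, 2), c(2, 3, 4), c(1, 0.5, 0.5))
  got <- is_min_l1_pairs(s1)
  expect_false(c(got))
  expect_equal(attr(got, "violation"), c(i = 1, j = 2, k = 4))

  s2 <- pair_coefficients(4, c(1, 1, 2), c(2, 3, 4), c(1, 0.5, -0.5))
  expect_true(c(is_min_l1_pairs(s2)))

  expect_true(is_min_l1_pairs(pair_coefficients(6)))
})

test_that("norm identity holds exactly when the minimum-L1 condition holds", {
  withr::local_seed(101)
  hits <- 0
  for (i in 1:300) {
    a <- random_alpha()
    l1a <- sum(abs(a$value))
    l1b <- sum(abs(beta_from_alpha(a)))
    if (isTRUE(c(is_min_l1_pairs(a)))) {
      hits <- hits + 1
      expect_equal(l1a, l1b / 2, tolerance = 1e-12)
    } else {
      expect_gt(l1a, l1b / 2)
    }
  }
  expect_gt(hits, 10) # both branches must actually be exercised
})

test_that("uniqueness requires a common hub gene, matching the hub identity", {
  s3 <- pair_coefficients(4, c(1, 1, 1), c(2, 3, 4), c(1, 0.5, 0.5))
  got <- is_unique_min_l1(s3)
  expect_true(c(got))
  expect_equal(attr(got, "hub"), 1)

  s2 <- pair_coefficients(4, c(1, 1, 2), c(2, 3, 4), c(1, 0.5, -0.5))
  expect_false(c(is_unique_min_l1(s2)))
  expect_true(c(is_unique_min_l1(pair_coefficients(3))))

  # star representations: the hub carries half the total gene-level mass
  withr::local_seed(202)
  for (i in 1:50) {
    p <- sample(4:10, 1)
    hub <- sample.int(p, 1)
    others <- setdiff(seq_len(p), hub)[seq_len(sample.int(p - 1, 1))]
    sgn <- sample(c(-1, 1), 1) # one common sign keeps it minimum-L1
    w <- sgn * stats::runif(length(others), 0.1, 2)
    a <- matrix_as_alpha({
      M <- matrix(0, p, p); M[hub, others] <- w; M[others, hub] <- -w; M
    })
    expect_true(c(is_unique_min_l1(a)))
    beta <- beta_from_alpha(a)
    j <- which.max(abs(beta))
    expect_equal(abs(beta[j]), sum(abs(beta[-j])), tolerance = 1e-12)
  }
})

test_that("support counts satisfy the structural bounds on random alphas", {
  s3 <- pair_coefficients(4, c(1, 1, 1), c(2, 3, 4), c(1, 0.5, 0.5))
  r3 <- pair_support_summary(s3)
  expect_equal(r3$A, 3L); expect_equal(r3$B, 4L)
  expect_equal(r3$B, r3$A + 1L)

  s1 <- pair_coefficients(4, c(1, 1, 2), c(2, 3, 4), c(1, 0.5, 0.5))
  r1 <- pair_support_summary(s1)
  expect_equal(r1$A, 3L); expect_equal(r1$B, 4L)
  expect_equal(beta_from_alpha(s1), c(1.5, -0.5, -0.5, -0.5))

  r0 <- pair_support_summary(pair_coefficients(5))
  expect_equal(r0$A, 0L); expect_equal(r0$B, 0L)

  withr::local_seed(303)
  for (i in 1:1000) {
    a <- random_alpha()
    r <- pair_support_summary(a)
    expect_lte(r$B, 2 * r$A)
    if (r$min_l1) expect_lte(2 * sqrt(r$A), r$B)
    if (r$unique_min_l1 && r$A > 0) expect_equal(r$B, r$A + 1L)
    if (r$unique_min_l1) expect_true(r$min_l1)
    # brute-force recount from the dense antisymmetric matrix
    M <- alpha_as_matrix(a)
    expect_equal(r$A, sum(M[upper.tri(M)] != 0))
    expect_equal(r$B, sum(abs(rowSums(M)) > 1e-10))
  }
})

test_that("gene sums are conserved and cycles are gauge freedoms", {
  withr::local_seed(404)
  for (i in 1:200) {
    a <- random_alpha(p = sample(4:10, 1))
    beta <- beta_from_alpha(a)
    expect_lte(abs(sum(beta)), 1e-12 * max(1, sum(abs(a$value))))
    expect_equal(beta, beta_by_rowsum(a), tolerance = 1e-12)

    # add a constant along a random cycle: beta must not move
    M <- alpha_as_matrix(a)
    k <- sample(3:a$p, 1)
    cyc <- sample.int(a$p, k)
    cst <- stats::rnorm(1)
    for (e in seq_len(k)) {
      from <- cyc[e]; to <- cyc[if (e == k) 1 else e + 1]
      M[from, to] <- M[from, to] + cst
      M[to, from] <- M[to, from] - cst
    }
    expect_equal(beta_from_alpha(matrix_as_alpha(M)), beta,
                 tolerance = 1e-10)
  }
})

test_that("pair tables round-trip through delimited text", {
  a <- pair_coefficients(4, c(1, 2), c(3, 4), c(0.25, -1.5),
                         gene_ids = c("TP53", "KRT15", "PTPRR", "GAPDH"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(a, path)
  b <- read_pairs(path, gene_ids = c("TP53", "KRT15", "PTPRR", "GAPDH"))
  expect_equal(a$j, b$j); expect_equal(a$k, b$k)
  expect_equal(a$value, b$value)
  expect_error(read_pairs(path), "gene_ids")
})
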
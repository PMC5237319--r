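make_pair <- function(truth, imputed, mask) {
  dimnames(truth) <- list(paste0("g", seq_len(nrow(truth))),
                          paste0("s", seq_len(ncol(truth))))
  dimnames(imputed) <- dimnames(truth)
  list(complete = expr_matrix(truth),
       masked = mask_matrix(expr_matrix(truth), mask, check_retention = FALSE),
       result = imputation_result("test", imputed))
}

test_that("inv_nrmse: hand-computed value, cap, and affine invariance", {
  truth <- matrix(c(0, 2, 5, 5, 5, 5), 2, 3)
  imputed <- matrix(c(1, 1, 5, 5, 5, 5), 2, 3)
  mask <- matrix(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE), 2, 3)
  f <- make_pair(truth, imputed, mask)
  # true masked {0, 2}: population SD = 1; imputed {1, 1}: RMSE = 1 -> 1/NRMSE = 1
  expect_equal(index_inv_nrmse(f$complete, f$result, f$masked)$value, 1)

  # perfect imputation hits the cap
  g <- make_pair(truth, truth, mask)
  expect_identical(index_inv_nrmse(g$complete, g$result, g$masked)$value, 1e12)

  # affine transform of both matrices leaves the score unchanged
  set.seed(1)
  t2 <- matrix(rnorm(40), 8, 5)
  i2 <- t2 + matrix(rnorm(40, sd = 0.3), 8, 5)
  m2 <- matrix(FALSE, 8, 5); m2[sample(40, 7)] <- TRUE
  a <- make_pair(t2, i2, m2)
  b <- make_pair(3 - 2 * t2, 3 - 2 * i2, m2)
  expect_equal(index_inv_nrmse(a$complete, a$result, a$masked)$value,
               index_inv_nrmse(b$complete, b$result, b$masked)$value)

  # degenerate mask: constant true values
  h <- make_pair(matrix(5, 3, 4), matrix(5, 3, 4),
                 {m <- matrix(FALSE, 3, 4); m[1, 1:2] <- TRUE; m})
  expect_error(index_inv_nrmse(h$complete, h$result, h$masked), "zero spread")
  expect_error(index_inv_nrmse(a$complete, a$result,
                               make_pair(t2, i2, matrix(FALSE, 8, 5))$masked),
               "non-empty")
})

test_that("inv_nrmse matches a naive reference on randomized inputs", {
  set.seed(42)
  for (trial in 1:1000) {
    n <- sample(3:8, 1); s <- sample(3:6, 1)
    truth <- matrix(rnorm(n * s), n, s)
    imputed <- truth + matrix(rnorm(n * s, sd = 0.5), n, s)
    mask <- matrix(FALSE, n, s)
    mask[sample(n * s, sample(2:5, 1))] <- TRUE
    f <- make_pair(truth, imputed, mask)
    got <- index_inv_nrmse(f$complete, f$result, f$masked)$value
    tv <- truth[mask]; iv <- imputed[mask]
    want <- 1 / (sqrt(sum((iv - tv)^2) / length(tv)) /
                   sqrt(sum((tv - mean(tv))^2) / length(tv)))
    expect_equal(got, want)
  }
})

test_that("cpp pair counting matches exhaustive pair enumeration", {
  # worked example: complete {ABC}{DEF}, imputed {AB}{CDEF} -> 4/6
  cl_c <- c(1, 1, 1, 2, 2, 2)
  cl_i <- c(1, 1, 2, 2, 2, 2)
  expect_equal(mvibench:::pairs_shared(cl_c, cl_i) / mvibench:::pairs_within(cl_c), 4 / 6)

  naive <- function(a, b) {
    n <- length(a); num <- 0; den <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      if (a[i] == a[j]) {
        den <- den + 1
        if (b[i] == b[j]) num <- num + 1
      }
    }
    c(num, den)
  }
  set.seed(7)
  for (trial in 1:1000) {
    n <- sample(4:12, 1)
    a <- sample(1:3, n, replace = TRUE)
    b <- sample(1:3, n, replace = TRUE)
    nd <- naive(a, b)
    expect_identical(as.numeric(mvibench:::pairs_shared(a, b)), nd[1])
    expect_identical(as.numeric(mvibench:::pairs_within(a)), nd[2])
  }
})

test_that("cpp is 1 for identical matrices and invariant to cluster relabeling", {
  ds <- generate_complete(synthetic_spec(n_genes = 60, seed = 3))
  r <- imputation_result("identity", ds$matrix$values)
  sc <- index_cpp(ds$matrix, r, k_clusters = 3, seed = 9)
  expect_identical(sc$value, 1)
  # the value depends only on the co-clustering structure, not on label ids
  mm <- make_mask(ds$matrix, 0.10, seed = 5)
  imp <- impute(mm, "zero")
  s1 <- index_cpp(ds$matrix, imp, k_clusters = 3, seed = 9)
  perm <- s1$components$clustering_imputed
  relabeled <- c(3, 1, 2)[perm]
  expect_identical(mvibench:::pairs_shared(s1$components$clustering_complete, relabeled),
                   s1$components$pairs_preserved)
})

test_that("cpp is 0 when the imputed clustering splits every complete pair", {
  cl_c <- c(1, 1, 2, 2)      # pairs: {12}, {34}
  cl_i <- c(1, 2, 1, 2)      # both split
  expect_identical(mvibench:::pairs_shared(cl_c, cl_i) / mvibench:::pairs_within(cl_c), 0)
})

test_that("blci: perfect, anti-perfect and the 7/12 worked example", {
  de_row <- function() c(0, 0, 5, 5)
  flat_row <- function() rep(0, 4)
  groups <- c("a", "a", "b", "b")
  build <- function(de_rows, n = 10) {
    v <- t(sapply(seq_len(n), function(i) if (i %in% de_rows) de_row() else flat_row()))
    v
  }
  truth <- build(1:4)
  f <- make_pair(truth, truth, matrix(FALSE, 10, 4))
  expect_identical(index_blci(f$complete, f$result, groups = groups)$value, 1)

  anti <- build(5:10)
  fa <- make_pair(truth, anti, matrix(FALSE, 10, 4))
  expect_identical(index_blci(fa$complete, fa$result, groups = groups)$value, -1)

  # |D_o| = 4, |D_o n D_i| = 3, |D_o^c n D_i^c| = 5 -> 3/4 + 5/6 - 1 = 7/12
  imp <- build(c(1, 2, 3, 5))
  fb <- make_pair(truth, imp, matrix(FALSE, 10, 4))
  expect_equal(index_blci(fb$complete, fb$result, groups = groups)$value, 7 / 12)

  # swapping the two group labels changes nothing
  expect_identical(index_blci(fb$complete, fb$result, groups = rev(groups))$value,
                   index_blci(fb$complete, fb$result, groups = groups)$value)

  # degenerate DE sets are rejected
  all_flat <- build(integer(0))
  fc <- make_pair(all_flat, all_flat, matrix(FALSE, 10, 4))
  expect_error(index_blci(fc$complete, fc$result, groups = groups), "blci undefined")
})

test_that("blci matches a naive t.test-based reference on random matrices", {
  set.seed(99)
  groups <- rep(c("a", "b"), each = 3)
  for (trial in 1:200) {
    n <- 8
    truth <- matrix(rnorm(n * 6), n, 6) + cbind(matrix(0, n, 3), matrix(rep(rbinom(n, 1, 0.4) * 2, 3), n, 3))
    imputed <- truth + matrix(rnorm(n * 6, sd = 0.4), n, 6)
    d_o <- apply(truth, 1, function(v) stats::t.test(v[1:3], v[4:6])$p.value < 0.05)
    d_i <- apply(imputed, 1, function(v) stats::t.test(v[1:3], v[4:6])$p.value < 0.05)
    if (!any(d_o) || all(d_o)) next
    want <- sum(d_o & d_i) / sum(d_o) + sum(!d_o & !d_i) / sum(!d_o) - 1
    f <- make_pair(truth, imputed, matrix(FALSE, n, 6))
    expect_equal(index_blci(f$complete, f$result, groups = groups)$value, want)
  }
})

test_that("median inv_nrmse does not increase with added noise", {
  ds <- generate_complete(synthetic_spec(n_genes = 80, seed = 17))
  mm <- make_mask(ds$matrix, 0.10, seed = 18)
  sds <- c(0.1, 0.5, 1.5)
  med <- sapply(sds, function(noise) {
    stats::median(sapply(1:50, function(s) {
      set.seed(s)
      imp <- ds$matrix$values
      imp[mm$mask] <- imp[mm$mask] + rnorm(sum(mm$mask), sd = noise)
      index_inv_nrmse(ds$matrix, imputation_result("noisy", imp), mm)$value
    }))
  })
  expect_true(all(diff(med) <= 0))
})
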
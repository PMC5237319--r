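all_algorithms <- function() list_imputers(include_plugins = FALSE)$algorithm_id

test_that("the registry exposes the twelve algorithms plus two baselines", {
  reg <- list_imputers(include_plugins = FALSE)
  expect_identical(nrow(reg), 14L)
  expect_identical(sum(reg$baseline), 2L)
  expect_setequal(reg$algorithm_id[reg$baseline], c("zero", "row_average"))
  expect_setequal(
    reg$algorithm_id[!reg$baseline],
    c("svd", "bpca", "knn", "sknn", "iknn", "ls",
      "lls", "slls", "ills", "shrink_lls", "shrink_slls", "shrink_ills")
  )
  expect_identical(sum(reg$category == "global"), 2L)
  expect_identical(sum(reg$category == "local"), 10L)
})

test_that("unknown algorithms and hyperparameters are rejected", {
  expect_error(imputer_spec("nope"), "unknown imputation algorithm")
  expect_error(imputer_spec("knn", list(bogus = 1)), "unknown hyperparameter")
  expect_silent(imputer_spec("knn", list(k = 3)))
})

test_that("baseline arithmetic: zero fills 0, row_average fills the observed mean", {
  v <- matrix(c(1, 3, 5, 2, 4, 6), 2, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
  m <- expr_matrix(v)
  mask <- matrix(c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE), 2, 3, byrow = TRUE)
  mm <- mask_matrix(m, mask)
  expect_identical(impute(mm, "zero")$imputed[1, 3], 0)
  expect_identical(impute(mm, "row_average")$imputed[1, 3], 2) # mean(1, 3)
})

test_that("zero-missing input is returned unchanged by every algorithm", {
  ds <- generate_complete(synthetic_spec(n_genes = 40, seed = 10))
  mm <- mask_matrix(ds$matrix, matrix(FALSE, 40, 6))
  for (id in all_algorithms()) {
    expect_identical(impute(mm, id)$imputed, ds$matrix$values, label = id)
  }
})

test_that("observed cells are preserved bit-exactly and output is complete", {
  ds <- generate_complete(synthetic_spec(n_genes = 60, seed = 20))
  for (p in c(0.05, 0.10)) {
    mm <- make_mask(ds$matrix, p, seed = 31)
    obs <- !mm$mask
    for (id in all_algorithms()) {
      r <- impute(mm, id)
      expect_false(anyNA(r$imputed), label = id)
      expect_identical(r$imputed[obs], ds$matrix$values[obs], label = id)
    }
  }
})

test_that("every algorithm is deterministic given the same input and seed", {
  ds <- generate_complete(synthetic_spec(n_genes = 50, seed = 30))
  mm <- make_mask(ds$matrix, 0.08, seed = 13)
  for (id in all_algorithms()) {
    expect_identical(impute(mm, id, seed = 5)$imputed,
                     impute(mm, id, seed = 5)$imputed, label = id)
  }
})

test_that("knn k = 1 copies a duplicated gene's value exactly", {
  set.seed(4)
  base <- matrix(rnorm(5 * 6), 5, 6)
  v <- rbind(base, base) # each gene duplicated once
  rownames(v) <- paste0("g", 1:10); colnames(v) <- paste0("s", 1:6)
  m <- expr_matrix(v)
  mask <- matrix(FALSE, 10, 6); mask[2, 4] <- TRUE
  mm <- mask_matrix(m, mask)
  for (id in c("knn", "sknn")) {
    expect_identical(impute(mm, id, params = list(k = 1))$imputed[2, 4], v[7, 4],
                     label = id)
  }
  # lls with k = 1 also reproduces the duplicate (coefficient 1 on a clone)
  expect_lt(abs(impute(mm, "lls", params = list(k = 1))$imputed[2, 4] - v[7, 4]), 1e-8)
})

test_that("equidistant knn neighbours are broken by ascending row index", {
  # genes 2 and 3 are reflections of gene 1 around its observed values:
  # equal distances but different values at the missing column
  v <- matrix(c(
    1, 2, 3, NA,
    1, 2, 4, 10,
    1, 2, 2, -10,
    9, 9, 9, 9
  ), 4, 4, byrow = TRUE)
  v[1, 4] <- 0 # placeholder; will be masked
  rownames(v) <- paste0("g", 1:4); colnames(v) <- paste0("s", 1:4)
  m <- expr_matrix(v)
  mask <- matrix(FALSE, 4, 4); mask[1, 4] <- TRUE
  mm <- mask_matrix(m, mask, check_retention = FALSE)
  got <- impute(mm, "knn", params = list(k = 1))$imputed[1, 4]
  expect_identical(got, 10) # gene 2 wins the tie against gene 3
  expect_identical(got, oracle_knn(mm, 1)[1, 4])
})

test_that("svd imputation exactly recovers low-rank structure", {
  # rank-1 outer product
  u <- 1:8; w <- c(2, -1, 0.5, 3, 1, -2)
  v <- outer(u, w)
  rownames(v) <- paste0("g", 1:8); colnames(v) <- paste0("s", 1:6)
  m <- expr_matrix(v)
  mm <- make_mask(m, 0.05, seed = 3)
  r <- impute(mm, "svd", params = list(rank = 1, tol = 1e-12, max_iter = 500))
  expect_lt(max(abs(r$imputed - v)), 1e-6)

  # zero-noise 2-cluster time course has exactly two distinct rows (rank 2)
  ds <- generate_timecourse(synthetic_spec(n_genes = 80, n_samples = 8,
                                           n_clusters = 2, noise_sd = 0, seed = 6))
  expect_identical(qr(ds$matrix$values)$rank, 2L)
  mm2 <- make_mask(ds$matrix, 0.05, seed = 8)
  r2 <- impute(mm2, "svd", params = list(rank = 2, tol = 1e-12, max_iter = 500))
  expect_lt(max(abs(r2$imputed - ds$matrix$values)), 1e-4)

  expect_error(impute(mm2, "svd", params = list(rank = 10)), "rank")
})

test_that("svd on an all-zero matrix imputes zeros", {
  v <- matrix(0, 10, 5, dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  mask <- matrix(FALSE, 10, 5); mask[3, 2] <- TRUE; mask[7, 4] <- TRUE
  mm <- mask_matrix(expr_matrix(v), mask)
  expect_identical(unname(impute(mm, "svd", params = list(rank = 1))$imputed[mask]), c(0, 0))
})

test_that("lls recovers an exact linear model and ls an exact affine one", {
  set.seed(9)
  n1 <- rnorm(8); n2 <- rnorm(8)
  target <- 1.5 * n1 - 2 * n2
  # filler genes offset far away so n1/n2 are the nearest neighbours
  v <- rbind(target, n1, n2, matrix(rnorm(4 * 8) + 10, 4, 8))
  rownames(v) <- paste0("g", 1:7); colnames(v) <- paste0("s", 1:8)
  mask <- matrix(FALSE, 7, 8); mask[1, c(3, 6)] <- TRUE
  mm <- mask_matrix(expr_matrix(v), mask)
  r <- impute(mm, "lls", params = list(k = 2))
  expect_lt(max(abs(r$imputed[1, c(3, 6)] - target[c(3, 6)])), 1e-8)
  # with zero residuals the shrinkage factor is 1: shrink_lls == lls
  expect_identical(impute(mm, "shrink_lls", params = list(k = 2))$imputed, r$imputed)

  x <- rnorm(8)
  v2 <- rbind(2 * x + 1, x, matrix(rnorm(2 * 8), 2, 8))
  rownames(v2) <- paste0("g", 1:4); colnames(v2) <- paste0("s", 1:8)
  mask2 <- matrix(FALSE, 4, 8); mask2[1, 5] <- TRUE
  mm2 <- mask_matrix(expr_matrix(v2), mask2)
  r2 <- impute(mm2, "ls", params = list(k = 1))
  expect_lt(abs(r2$imputed[1, 5] - (2 * x[5] + 1)), 1e-9)
})

test_that("ls falls back to the row average when every neighbour is constant", {
  v <- rbind(c(1, 2, 3, 4), matrix(5, 3, 4))
  rownames(v) <- paste0("g", 1:4); colnames(v) <- paste0("s", 1:4)
  mask <- matrix(FALSE, 4, 4); mask[1, 2] <- TRUE
  mm <- mask_matrix(expr_matrix(v), mask, check_retention = FALSE)
  r <- impute(mm, "ls")
  expect_identical(r$diagnostics$fallbacks, 1L)
  expect_identical(r$imputed[1, 2], mean(c(1, 3, 4)))
})

test_that("bpca beats row average on low-rank data and shrinks unused factors", {
  ds <- generate_timecourse(synthetic_spec(n_genes = 100, n_samples = 8, n_clusters = 2,
                                           noise_sd = 0.05, seed = 12))
  mm <- make_mask(ds$matrix, 0.05, seed = 21)
  truth <- ds$matrix$values[mm$mask]
  mse <- function(r) mean((r$imputed[mm$mask] - truth)^2)
  expect_lt(mse(impute(mm, "bpca")), mse(impute(mm, "row_average")))
  expect_error(impute(mm, "bpca", params = list(n_factors = 8)), "n_factors")
})

test_that("iterative variants terminate with honest diagnostics", {
  ds <- generate_complete(synthetic_spec(n_genes = 80, seed = 14))
  mm <- make_mask(ds$matrix, 0.10, seed = 15)
  r <- impute(mm, "iknn")
  expect_true(r$diagnostics$converged)
  expect_gte(r$diagnostics$iterations, 2L)
  # lls iteration oscillates at the noise floor on weakly structured data:
  # it must stop early (stall cutoff), flag non-convergence, and still
  # return a complete matrix
  for (id in c("ills", "shrink_ills")) {
    r <- impute(mm, id)
    expect_false(anyNA(r$imputed), label = id)
    expect_true(r$diagnostics$converged || r$diagnostics$stalled ||
                  r$diagnostics$iterations == 100L, label = id)
    expect_lt(r$diagnostics$iterations, 100L)
  }
  r <- impute(mm, "slls")
  expect_identical(r$diagnostics$fallbacks, 0L)
})
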
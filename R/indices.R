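# The three performance indices. Each compares one imputed matrix against
# the complete matrix it came from and returns a higher-is-better score:
#   inv_nrmse -- numerical similarity at the masked cells,
#   cpp       -- preservation of the gene clustering,
#   blci      -- concordance of the differentially-expressed gene lists.

index_ids <- function() c("inv_nrmse", "cpp", "blci")

new_index_score <- function(index_id, value, components) {
  structure(list(index_id = index_id, value = value, components = components),
            class = "index_score")
}

#' @export
print.index_score <- function(x, ...) {
  cat(sprintf("<index_score> %s = %g\n", x$index_id, x$value))
  invisible(x)
}

#' Inverse normalized root mean square error
#'
#' `NRMSE = sqrt(mean((imputed - true)^2 at masked cells)) / sd(true at
#' masked cells)` (population SD). The score is `1 / NRMSE`, capped at `1e12`
#' for a perfect imputation. With `normalization = "mean"`, the RMSE is
#' divided by the mean of the true masked values instead (the alternative
#' convention of the early KNN-imputation literature).
#'
#' @param complete The complete [expr_matrix].
#' @param result An [imputation_result] (or plain matrix).
#' @param masked The [mask_matrix] object the result was computed from.
#' @param normalization `"sd"` (default) or `"mean"`.
#' @return An `index_score` with components `nrmse`, `rmse`, `n_masked`.
#' @export
index_inv_nrmse <- function(complete, result, masked, normalization = c("sd", "mean")) {
  normalization <- match.arg(normalization)
  truth <- complete$values
  imp <- if (inherits(result, "imputation_result")) result$imputed else result
  stopifnot(identical(dim(truth), dim(imp)))
  cells <- masked$mask
  if (!any(cells)) abort("inv_nrmse needs a non-empty mask")
  tv <- truth[cells]; iv <- imp[cells]
  rmse <- sqrt(mean((iv - tv)^2))
  denom <- if (normalization == "sd") {
    sqrt(mean((tv - mean(tv))^2)) # population SD
  } else {
    abs(mean(tv))
  }
  if (denom == 0) {
    abort("degenerate mask: the true values at the masked cells have zero spread")
  }
  nrmse <- rmse / denom
  value <- if (nrmse < 1e-12) 1e12 else 1 / nrmse
  new_index_score("inv_nrmse", value,
                  list(nrmse = nrmse, rmse = rmse, n_masked = sum(cells)))
}

# Co-clustered unordered pair counts from one or two label vectors, via the
# contingency table (sum over cells of choose(n, 2)).
pairs_within <- function(labels) sum(choose(table(labels), 2))
pairs_shared <- function(a, b) sum(choose(table(a, b), 2))

#' Cluster pair proportion
#'
#' Genes of the complete and of the imputed matrix are clustered separately
#' with k-means (same `k`, same seed, `nstart` restarts, best inertia kept).
#' The score is the fraction of unordered gene pairs co-clustered in the
#' complete matrix's clustering that are still co-clustered in the imputed
#' matrix's clustering.
#'
#' @inheritParams index_inv_nrmse
#' @param k_clusters Number of k-means clusters (default 10).
#' @param seed Seed shared by both clusterings, making the index
#'   deterministic.
#' @param nstart k-means restarts.
#' @param complete_clustering Optional precomputed clustering of the complete
#'   matrix (integer vector), to avoid re-clustering it for every algorithm.
#' @return An `index_score` with components `pairs_complete`,
#'   `pairs_preserved` and both label vectors.
#' @export
index_cpp <- function(complete, result, k_clusters = 10L, seed = 1L, nstart = 10L,
                      complete_clustering = NULL) {
  imp <- if (inherits(result, "imputation_result")) result$imputed else result
  if (k_clusters < 2L) abort("cpp needs k_clusters >= 2")
  if (nrow(complete$values) < k_clusters) abort("cpp needs at least k_clusters genes")
  cl_c <- complete_clustering %||% cluster_genes(complete$values, k_clusters, seed, nstart)
  cl_i <- cluster_genes(imp, k_clusters, seed, nstart)
  p_complete <- pairs_within(cl_c)
  if (p_complete == 0) abort("cpp undefined: the complete clustering has only singleton clusters")
  preserved <- pairs_shared(cl_c, cl_i)
  new_index_score("cpp", preserved / p_complete,
                  list(pairs_complete = p_complete, pairs_preserved = preserved,
                       clustering_complete = cl_c, clustering_imputed = cl_i))
}

#' @rdname index_cpp
#' @param values Numeric genes x samples matrix to cluster.
#' @export
cluster_genes <- function(values, k_clusters, seed = 1L, nstart = 10L) {
  with_seed(seed, stats::kmeans(values, centers = k_clusters, nstart = nstart,
                                iter.max = 100L)$cluster)
}

#' Biomarker list concordance index
#'
#' With `D_o` the genes called differentially expressed (Welch two-sample
#' t-test, `p < alpha`) on the complete matrix and `D_i` the same on the
#' imputed matrix:
#' `BLCI = |D_o ∩ D_i| / |D_o| + |D_o^c ∩ D_i^c| / |D_o^c| - 1`,
#' ranging from -1 to 1 with 1 for perfect concordance.
#'
#' @inheritParams index_inv_nrmse
#' @param groups Two-level sample assignment; defaults to the complete
#'   matrix's labels, or (for unlabeled time-course data) to first half vs
#'   second half of the columns, with a warning.
#' @param alpha Per-gene significance threshold (default 0.05, uncorrected).
#' @return An `index_score` with set-size components.
#' @export
index_blci <- function(complete, result, groups = NULL, alpha = 0.05) {
  imp <- if (inherits(result, "imputation_result")) result$imputed else result
  groups <- groups %||% complete$groups
  if (is.null(groups)) {
    warn("no group labels: defaulting to first half vs second half of the samples")
    half <- ncol(complete$values) %/% 2L
    groups <- rep(c("group1", "group2"), c(half, ncol(complete$values) - half))
  }
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) abort("blci needs exactly two sample groups")
  g1 <- groups == lv[1L]; g2 <- groups == lv[2L]
  if (sum(g1) < 2L || sum(g2) < 2L) abort("blci needs >= 2 samples per group")
  d_o <- welch_p_rows(complete$values, g1, g2) < alpha
  d_i <- welch_p_rows(imp, g1, g2) < alpha
  n <- length(d_o)
  if (!any(d_o) || all(d_o)) {
    abort(paste0(
      "blci undefined: the complete matrix yields ", sum(d_o),
      " of ", n, " DE genes at alpha = ", alpha,
      "; adjust alpha or the synthetic effect size"
    ))
  }
  tp <- sum(d_o & d_i); tn <- sum(!d_o & !d_i)
  value <- tp / sum(d_o) + tn / sum(!d_o) - 1
  new_index_score("blci", value,
                  list(n_de_complete = sum(d_o), n_de_imputed = sum(d_i),
                       n_agree_de = tp, n_agree_non_de = tn, n_genes = n))
}

# Vectorized per-row Welch two-sample t-test p-values. Degenerate rows (zero
# pooled standard error) get p = 1 when the means agree and p = 0 otherwise.
welch_p_rows <- function(x, g1, g2) {
  x1 <- x[, g1, drop = FALSE]; x2 <- x[, g2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

# Internal dispatcher used by the evaluation engine.
score_index <- function(index_id, complete, result, masked, config, cache = NULL) {
  switch(index_id,
    inv_nrmse = index_inv_nrmse(complete, result, masked,
                                normalization = config$nrmse_normalization),
    cpp = index_cpp(complete, result, k_clusters = config$cpp_k,
                    seed = config$cpp_seed, nstart = config$cpp_nstart,
                    complete_clustering = cache),
    blci = index_blci(complete, result, alpha = config$blci_alpha),
    abort(sprintf("unknown index '%s'", index_id))
  )
}
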
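# Shared fixtures and independent brute-force oracles.

# Fixed 6 x 4 matrix with generic values: distinct pairwise distances and
# correlations, no accidental ties.
tiny_matrix <- function() {
  v <- matrix(c(
    1.214, 2.731, 0.842, 3.105,
    2.110, 1.004, 2.915, 0.557,
    1.873, 2.405, 1.332, 2.688,
    0.451, 3.012, 1.760, 2.241,
    2.904, 0.618, 2.377, 1.095,
    1.508, 1.992, 2.063, 1.441
  ), nrow = 6, byrow = TRUE)
  dimnames(v) <- list(paste0("g", 1:6), paste0("s", 1:4))
  expr_matrix(v)
}

# All masks with exactly `n_cells` masked entries of a g x s matrix.
enumerate_masks <- function(complete, n_cells) {
  dims <- dim(complete$values)
  combos <- utils::combn(prod(dims), n_cells)
  lapply(seq_len(ncol(combos)), function(j) {
    m <- matrix(FALSE, dims[1], dims[2])
    m[combos[, j]] <- TRUE
    mask_matrix(complete, m, check_retention = FALSE)
  })
}

# ---- independent oracles ----------------------------------------------------

# Brute-force KNN: per missing cell, candidates observed at that column with
# at least one jointly observed column; RMS distance over shared columns;
# ties by row index; inverse-distance weights.
oracle_knn <- function(masked, k) {
  x <- masked_values(masked)
  out <- x
  for (t in seq_len(nrow(x))) {
    for (cc in which(is.na(x[t, ]))) {
      cand <- list()
      for (h in seq_len(nrow(x))) {
        if (h == t || is.na(x[h, cc])) next
        shared <- which(!is.na(x[t, ]) & !is.na(x[h, ]))
        if (!length(shared)) next
        d <- sqrt(mean((x[t, shared] - x[h, shared])^2))
        cand[[length(cand) + 1]] <- c(h = h, d = d)
      }
      if (!length(cand)) {
        obs <- x[t, !is.na(x[t, ])]
        out[t, cc] <- if (length(obs)) mean(obs) else 0
        next
      }
      tab <- do.call(rbind, cand)
      tab <- tab[order(tab[, "d"], tab[, "h"]), , drop = FALSE]
      nb <- tab[seq_len(min(k, nrow(tab))), , drop = FALSE]
      w <- 1 / (nb[, "d"] + 1e-10)
      out[t, cc] <- sum(w * x[nb[, "h"], cc]) / sum(w)
    }
  }
  out
}

# Brute-force LS: per missing cell, per-candidate simple regression via lm()
# on jointly observed columns (>= min_shared, non-constant on both sides),
# top-k by |r| (ties by row index), weights (r^2/(1-r^2+eps))^2.
oracle_ls <- function(masked, k, eps = 1e-6, min_shared = 3) {
  x <- masked_values(masked)
  out <- x
  for (t in seq_len(nrow(x))) {
    for (cc in which(is.na(x[t, ]))) {
      h_id <- integer(0); r_abs <- numeric(0); pred <- numeric(0)
      for (h in seq_len(nrow(x))) {
        if (h == t || is.na(x[h, cc])) next
        shared <- which(!is.na(x[t, ]) & !is.na(x[h, ]))
        if (length(shared) < min_shared) next
        yt <- x[t, shared]; yh <- x[h, shared]
        if (stats::sd(yt) == 0 || stats::sd(yh) == 0) next
        r <- stats::cor(yt, yh)
        if (!is.finite(r)) next
        fit <- stats::lm(yt ~ yh)
        h_id <- c(h_id, h)
        r_abs <- c(r_abs, abs(r))
        pred <- c(pred, unname(stats::predict(fit, data.frame(yh = x[h, cc]))))
      }
      if (!length(h_id)) {
        obs <- x[t, !is.na(x[t, ])]
        out[t, cc] <- if (length(obs)) mean(obs) else 0
        next
      }
      ord <- order(-r_abs, h_id)
      use <- ord[seq_len(min(k, length(ord)))]
      r2 <- r_abs[use]^2
      w <- (r2 / (1 - r2 + eps))^2
      if (sum(w) <= 0) w <- rep(1, length(use))
      out[t, cc] <- sum(w * pred[use]) / sum(w)
    }
  }
  out
}

# SVD-based pseudoinverse, written out here so the oracle does not share the
# implementation's linear-algebra path.
oracle_pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * max(s$d, 0)
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*% ((1 / s$d[keep]) * t(s$u[, keep, drop = FALSE]))
}

# Brute-force LLS: per target gene, neighbours are fully observed genes
# ranked by Euclidean distance over the target's observed columns (ties by
# row index); minimum-norm least squares of the observed part on the
# neighbour block; same combination predicts the missing part.
oracle_lls <- function(masked, k) {
  x <- masked_values(masked)
  out <- x
  pool <- which(rowSums(is.na(x)) == 0)
  for (t in seq_len(nrow(x))) {
    miss <- which(is.na(x[t, ]))
    if (!length(miss)) next
    obs <- which(!is.na(x[t, ]))
    cand <- setdiff(pool, t)
    if (!length(cand)) {
      obsv <- x[t, obs]
      out[t, miss] <- if (length(obsv)) mean(obsv) else 0
      next
    }
    d <- sapply(cand, function(h) sqrt(sum((x[t, obs] - x[h, obs])^2)))
    nb <- cand[order(d, cand)][seq_len(min(k, length(cand)))]
    A <- t(x[nb, obs, drop = FALSE])      # |obs| x k
    coef <- oracle_pinv(A) %*% x[t, obs]
    out[t, miss] <- t(x[nb, miss, drop = FALSE]) %*% coef
  }
  out
}

# ---- plugin fixtures --------------------------------------------------------

# Write an executable Rscript plugin to a temp dir. `body` is R code reading
# `inp`/`outp` TSV paths from commandArgs.
write_plugin_script <- function(body, name = "plugin") {
  path <- file.path(tempfile(paste0("mvib_", name, "_")), paste0(name, ".R"))
  dir.create(dirname(path))
  writeLines(c(
    "#!/usr/bin/env Rscript",
    "args <- commandArgs(trailingOnly = TRUE)",
    "inp <- args[[length(args) - 1]]; outp <- args[[length(args)]]",
    "tab <- read.delim(inp, check.names = FALSE)",
    "m <- as.matrix(tab[, -1, drop = FALSE]); rownames(m) <- tab[[1]]",
    body,
    "out <- cbind(gene_id = rownames(m), as.data.frame(m))",
    "write.table(out, outp, sep = '\\t', quote = FALSE, row.names = FALSE)"
  ), path)
  Sys.chmod(path, "0755")
  path
}

zero_plugin <- function() {
  plugin_imputer("zerocopy", write_plugin_script("m[is.na(m)] <- 0", "zerocopy"))
}
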
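# Regression-based local imputers.
#
# ls: per missing cell, the k genes most correlated with the target over
# jointly observed columns each contribute a simple least-squares prediction;
# predictions are combined with weights (r^2 / (1 - r^2 + eps))^2.
#
# lls family: the target's observed part is expressed as a linear
# combination of the k nearest complete genes (minimum-norm least squares);
# the same combination of the neighbours' values fills the missing columns.
# slls processes genes sequentially (imputed genes re-enter the pool), ills
# iterates from a row-average start, and the shrinkage variants scale the
# fitted coefficients by a positive-part James-Stein factor before
# prediction.

ls_default_k <- 10L

impute_ls <- function(masked, params) {
  x <- masked_values(masked) # never updated: plain ls has no sequential feedback
  out <- x
  k <- params$k
  eps <- params$eps
  min_shared <- params$min_shared
  fallbacks <- 0L
  rm_obs <- row_means_obs(x)
  targets <- which(rowSums(is.na(x)) > 0L)
  for (t in targets) {
    fit <- ls_pairwise_fits(x, t, min_shared)
    for (cc in which(is.na(x[t, ]))) {
      cand <- which(fit$usable & !is.na(x[, cc]))
      if (!length(cand)) {
        out[t, cc] <- rm_obs[t]
        fallbacks <- fallbacks + 1L
        next
      }
      # k most correlated, ties by row index
      cand <- cand[order(-abs(fit$r[cand]), cand)]
      use <- cand[seq_len(min(k, length(cand)))]
      r2 <- fit$r[use]^2
      w <- (r2 / (1 - r2 + eps))^2
      if (sum(w) <= 0) w <- rep(1, length(use))
      pred <- fit$intercept[use] + fit$slope[use] * x[use, cc]
      out[t, cc] <- sum(w * pred) / sum(w)
    }
  }
  list(imputed = out, diagnostics = list(fallbacks = fallbacks))
}

# Pairwise simple-regression fits of target gene t on every other gene over
# their jointly observed columns (vectorized sufficient statistics). A gene
# is usable when it shares at least `min_shared` observed columns with the
# target and neither side is constant over the shared columns.
ls_pairwise_fits <- function(x, t, min_shared) {
  obs_t <- which(!is.na(x[t, ]))
  M <- x[, obs_t, drop = FALSE]
  xt <- x[t, obs_t]
  sh <- !is.na(M)
  M0 <- M; M0[!sh] <- 0
  n <- rowSums(sh)
  sx <- rowSums(M0)
  sxx <- rowSums(M0^2)
  st <- drop(sh %*% xt)
  stt <- drop(sh %*% xt^2)
  sxt <- drop(M0 %*% xt)
  vx <- n * sxx - sx^2
  vt <- n * stt - st^2
  cv <- n * sxt - sx * st
  r <- cv / sqrt(pmax(vx * vt, 0))
  slope <- cv / vx
  intercept <- (st - slope * sx) / n
  usable <- n >= min_shared & is.finite(r) & vx > 1e-12 * pmax(n, 1) & vt > 1e-12 * pmax(n, 1)
  usable[t] <- FALSE
  list(r = r, slope = slope, intercept = intercept, usable = usable)
}

lls_resolve_k <- function(k, n_genes) {
  if (!is.na(k)) return(as.integer(k))
  max(5L, min(as.integer(round_half_away(0.1 * n_genes)), 150L))
}

# One LLS regression: express target's observed part as a combination of the
# neighbour block (minimum-norm via pseudoinverse), optionally shrink the
# coefficients, and predict the missing part.
lls_predict <- function(x, t, nb, obs_cols, miss_cols, shrink) {
  A <- x[nb, obs_cols, drop = FALSE]      # k x |obs|
  w <- x[t, obs_cols]
  coef <- drop(MASS::ginv(t(A)) %*% w)
  if (shrink && length(nb) > 2L) {
    resid <- w - drop(t(A) %*% coef)
    df <- max(1L, length(obs_cols) - length(nb))
    sigma2 <- sum(resid^2) / df
    c2 <- sum(coef^2)
    if (c2 > 0) {
      coef <- coef * max(0, 1 - (length(nb) - 2L) * sigma2 / c2)
    }
  }
  drop(t(x[nb, miss_cols, drop = FALSE]) %*% coef)
}

# Neighbour selection for plain lls: only genes fully observed (the target's
# observed plus missing columns cover every column), ranked by Euclidean
# distance over the target's observed columns, ties by row index.
lls_neighbours <- function(x, t, obs_cols, pool, k) {
  cand <- setdiff(pool, t)
  if (!length(cand)) return(integer(0))
  d <- sqrt(rowSums(sweep(x[cand, obs_cols, drop = FALSE], 2L, x[t, obs_cols], "-")^2))
  cand[order(d, cand)][seq_len(min(k, length(cand)))]
}

impute_lls <- function(masked, params, shrink = FALSE) {
  x <- masked_values(masked)
  k <- lls_resolve_k(params$k, nrow(x))
  fallbacks <- 0L; reduced <- 0L
  rm_obs <- row_means_obs(x)
  pool <- which(rowSums(is.na(x)) == 0L)
  for (t in which(rowSums(is.na(x)) > 0L)) {
    obs_cols <- which(!is.na(x[t, ]))
    miss_cols <- which(is.na(x[t, ]))
    nb <- lls_neighbours(x, t, obs_cols, pool, k)
    if (!length(nb)) {
      x[t, miss_cols] <- rm_obs[t]
      fallbacks <- fallbacks + length(miss_cols)
      next
    }
    if (length(nb) < k) reduced <- reduced + 1L
    x[t, miss_cols] <- lls_predict(x, t, nb, obs_cols, miss_cols, shrink)
  }
  list(imputed = x, diagnostics = list(fallbacks = fallbacks, k = k, k_reduced_genes = reduced))
}

impute_slls <- function(masked, params, shrink = FALSE) {
  x <- masked_values(masked)
  k <- lls_resolve_k(params$k, nrow(x))
  fallbacks <- 0L
  rm_obs <- row_means_obs(x)
  n_miss <- rowSums(is.na(x))
  pool <- which(n_miss == 0L)
  targets <- setdiff(order(n_miss, seq_along(n_miss)), which(n_miss == 0L))
  for (t in targets) {
    obs_cols <- which(!is.na(x[t, ]))
    miss_cols <- which(is.na(x[t, ]))
    nb <- lls_neighbours(x, t, obs_cols, pool, k)
    if (!length(nb) || !length(obs_cols)) {
      x[t, miss_cols] <- rm_obs[t]
      fallbacks <- fallbacks + length(miss_cols)
    } else {
      x[t, miss_cols] <- lls_predict(x, t, nb, obs_cols, miss_cols, shrink)
    }
    pool <- c(pool, t)
  }
  list(imputed = x, diagnostics = list(fallbacks = fallbacks, k = k))
}

impute_ills <- function(masked, params, shrink = FALSE) {
  x0 <- masked_values(masked)
  miss <- is.na(x0)
  x <- impute_row_average(masked, params)$imputed
  k <- lls_resolve_k(params$k, nrow(x))
  targets <- which(rowSums(miss) > 0L)
  obs_list <- lapply(targets, function(t) which(!miss[t, ]))
  miss_list <- lapply(targets, function(t) which(miss[t, ]))
  all_genes <- seq_len(nrow(x))
  iter <- 0L
  converged <- FALSE
  stalled <- FALSE
  best_delta <- Inf
  stall <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    x_new <- x
    for (i in seq_along(targets)) {
      t <- targets[i]
      nb <- lls_neighbours(x, t, obs_list[[i]], all_genes, k)
      x_new[t, miss_list[[i]]] <- lls_predict(x, t, nb, obs_list[[i]], miss_list[[i]], shrink)
    }
    # relative Frobenius change over the imputed cells
    delta <- sqrt(sum((x_new[miss] - x[miss])^2)) / (sqrt(sum(x[miss]^2)) + 1e-12)
    x <- x_new
    if (delta < params$tol) { converged <- TRUE; break }
    # neighbour reselection makes the iteration oscillate at the noise floor
    # on weakly structured data; stop once the change stops improving
    if (delta < best_delta) { best_delta <- delta; stall <- 0L }
    else if ((stall <- stall + 1L) >= 3L) { stalled <- TRUE; break }
  }
  list(imputed = x, diagnostics = list(iterations = iter, converged = converged,
                                       stalled = stalled, k = k))
}

lls_defaults <- list(k = NA_integer_, tol = 1e-4, max_iter = 100L)

register_imputer("ls", "Least squares (correlation-weighted)", "local", FALSE,
                 list(k = ls_default_k, eps = 1e-6, min_shared = 3L), impute_ls)
register_imputer("lls", "Local least squares", "local", FALSE, lls_defaults,
                 function(m, p) impute_lls(m, p, shrink = FALSE))
register_imputer("slls", "Sequential LLS", "local", FALSE, lls_defaults,
                 function(m, p) impute_slls(m, p, shrink = FALSE))
register_imputer("ills", "Iterative LLS", "local", FALSE, lls_defaults,
                 function(m, p) impute_ills(m, p, shrink = FALSE))
register_imputer("shrink_lls", "Shrinkage LLS", "local", FALSE, lls_defaults,
                 function(m, p) impute_lls(m, p, shrink = TRUE))
register_imputer("shrink_slls", "Shrinkage sequential LLS", "local", FALSE, lls_defaults,
                 function(m, p) impute_slls(m, p, shrink = TRUE))
register_imputer("shrink_ills", "Shrinkage iterative LLS", "local", FALSE, lls_defaults,
                 function(m, p) impute_ills(m, p, shrink = TRUE))
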
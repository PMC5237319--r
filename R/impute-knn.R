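# K-nearest-neighbour imputation family: knn, sknn (sequential), iknn
# (iterative).
#
# Distances are root mean squared differences over jointly observed columns,
# so genes with different missingness patterns are comparable. Ties are
# broken by ascending row index. A cell with no eligible neighbour falls
# back to the gene's observed row average (counted in diagnostics).

knn_weighted_mean <- function(values, dists, eps = 1e-10) {
  if (length(values) == 1L) return(values) # exact for a single neighbour
  w <- 1 / (dists + eps)
  sum(w * values) / sum(w)
}

# RMS distance from gene `t` (using its observed columns) to every gene, NA
# where no column is jointly observed.
knn_distances <- function(x, t, obs_cols) {
  xt <- x[, obs_cols, drop = FALSE]
  diff2 <- sweep(xt, 2L, xt[t, ], "-")^2
  shared <- rowSums(!is.na(diff2))
  d <- sqrt(rowSums(diff2, na.rm = TRUE) / shared)
  d[shared == 0L] <- NA_real_
  d[t] <- NA_real_
  d
}

impute_knn <- function(masked, params) {
  x <- masked_values(masked) # never updated: plain knn has no sequential feedback
  out <- x
  k <- params$k
  fallbacks <- 0L
  rm_obs <- row_means_obs(x)
  targets <- which(rowSums(is.na(x)) > 0L)
  for (t in targets) {
    miss_cols <- which(is.na(x[t, ]))
    obs_cols <- which(!is.na(x[t, ]))
    d <- if (length(obs_cols)) knn_distances(x, t, obs_cols) else rep(NA_real_, nrow(x))
    for (cc in miss_cols) {
      cand <- which(!is.na(x[, cc]) & !is.na(d))
      if (!length(cand)) {
        out[t, cc] <- rm_obs[t]
        fallbacks <- fallbacks + 1L
        next
      }
      ord <- cand[order(d[cand], cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      out[t, cc] <- knn_weighted_mean(x[nb, cc], d[nb])
    }
  }
  list(imputed = out, diagnostics = list(fallbacks = fallbacks))
}

impute_sknn <- function(masked, params) {
  x <- masked_values(masked)
  k <- params$k
  fallbacks <- 0L
  rm_obs <- row_means_obs(x)
  n_miss <- rowSums(is.na(x))
  pool <- which(n_miss == 0L)
  # ascending missing count, ties by row index
  targets <- setdiff(order(n_miss, seq_along(n_miss)), which(n_miss == 0L))
  for (t in targets) {
    miss_cols <- which(is.na(x[t, ]))
    obs_cols <- which(!is.na(x[t, ]))
    cand <- setdiff(pool, t)
    if (!length(cand) || !length(obs_cols)) {
      x[t, miss_cols] <- rm_obs[t]
      fallbacks <- fallbacks + length(miss_cols)
    } else {
      d <- sqrt(rowMeans(sweep(x[cand, obs_cols, drop = FALSE], 2L, x[t, obs_cols], "-")^2))
      ord <- cand[order(d, cand)]
      nb <- ord[seq_len(min(k, length(ord)))]
      dn <- d[match(nb, cand)]
      for (cc in miss_cols) x[t, cc] <- knn_weighted_mean(x[nb, cc], dn)
    }
    pool <- c(pool, t) # imputed gene joins the candidate pool as complete
  }
  list(imputed = x, diagnostics = list(fallbacks = fallbacks))
}

impute_iknn <- function(masked, params) {
  x0 <- masked_values(masked)
  miss <- is.na(x0)
  x <- impute_row_average(masked, params)$imputed
  k <- params$k
  targets <- which(rowSums(miss) > 0L)
  iter <- 0L
  converged <- FALSE
  stalled <- FALSE
  best_delta <- Inf
  stall <- 0L
  while (iter < params$max_iter) {
    iter <- iter + 1L
    x_new <- x
    for (t in targets) {
      others <- setdiff(seq_len(nrow(x)), t)
      d <- sqrt(rowMeans(sweep(x[others, , drop = FALSE], 2L, x[t, ], "-")^2))
      ord <- others[order(d, others)]
      nb <- ord[seq_len(min(k, length(ord)))]
      dn <- d[match(nb, others)]
      for (cc in which(miss[t, ])) {
        x_new[t, cc] <- knn_weighted_mean(x[nb, cc], dn)
      }
    }
    # relative Frobenius change over the imputed cells
    delta <- sqrt(sum((x_new[miss] - x[miss])^2)) / (sqrt(sum(x[miss]^2)) + 1e-12)
    x <- x_new
    if (delta < params$tol) { converged <- TRUE; break }
    # stop once the change stops improving (oscillation at the noise floor)
    if (delta < best_delta) { best_delta <- delta; stall <- 0L }
    else if ((stall <- stall + 1L) >= 3L) { stalled <- TRUE; break }
  }
  list(imputed = x, diagnostics = list(iterations = iter, converged = converged,
                                       stalled = stalled))
}

register_imputer("knn", "K-nearest neighbours", "local", FALSE,
                 list(k = 10L), impute_knn)
register_imputer("sknn", "Sequential KNN", "local", FALSE,
                 list(k = 10L), impute_sknn)
register_imputer("iknn", "Iterative KNN", "local", FALSE,
                 list(k = 10L, tol = 1e-4, max_iter = 100L), impute_iknn)
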
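# Global latent-model imputers: iterative low-rank SVD and variational
# Bayesian PCA with automatic relevance determination.

impute_svd <- function(masked, params) {
  x <- masked_values(masked)
  miss <- is.na(x)
  rank <- params$rank
  if (is.na(rank)) rank <- max(1L, as.integer(round_half_away(0.2 * ncol(x))))
  if (rank < 1L || rank > min(dim(x))) {
    abort(sprintf("svd rank %d out of bounds for a %d x %d matrix",
                  rank, nrow(x), ncol(x)))
  }
  x[miss] <- row_means_obs(x)[row(x)[miss]]
  iter <- 0L
  converged <- FALSE
  while (iter < params$max_iter) {
    iter <- iter + 1L
    sv <- svd(x, nu = rank, nv = rank)
    approx <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
    old <- x[miss]
    x[miss] <- approx[miss]
    rel <- sqrt(sum((x[miss] - old)^2)) / (sqrt(sum(old^2)) + 1e-12)
    if (rel < params$tol) { converged <- TRUE; break }
  }
  list(imputed = x, diagnostics = list(iterations = iter, converged = converged, rank = rank))
}

# Variational EM for Bayesian PCA with per-factor ARD precisions. Genes are
# observations of dimension d = n_samples; factor scores are integrated out
# per gene (grouped by missingness pattern), loadings, the noise precision
# and the ARD precisions are point-updated. Initialization is the SVD of the
# row-average fill, so the whole procedure is deterministic.
impute_bpca <- function(masked, params) {
  y <- masked_values(masked)
  miss <- is.na(y)
  d <- ncol(y); g <- nrow(y)
  q <- params$n_factors
  if (is.na(q)) q <- max(1L, d - 1L)
  if (q < 1L || q > d - 1L) {
    abort(sprintf("bpca needs 1 <= n_factors <= samples - 1, got %d for %d samples", q, d))
  }
  x0 <- y
  x0[miss] <- row_means_obs(y)[row(y)[miss]]
  mu <- colMeans(x0)
  sv <- svd(sweep(x0, 2L, mu), nu = 0L, nv = q)
  W <- sv$v %*% diag(sv$d[seq_len(q)] / sqrt(g), q, q)   # d x q
  tau <- 1 / max(mean((sweep(x0, 2L, mu))^2), 1e-6)
  alpha <- rep(1, q)

  pattern_key <- apply(!miss, 1L, function(o) paste(which(o), collapse = ","))
  groups <- split(seq_len(g), pattern_key)

  iter <- 0L
  converged <- FALSE
  theta_old <- c(W, mu)
  scores <- matrix(0, g, q)
  covs <- vector("list", length(groups))
  while (iter < params$max_iter) {
    iter <- iter + 1L
    # E-step: posterior of factor scores per missingness pattern
    SS <- matrix(0, q, q)                      # sum over genes of C_i
    SS_by_dim <- array(0, c(q, q, d))          # sum of (x x^T + C_i) over genes observing dim j
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      obs <- which(!miss[rows[1L], ])
      Wo <- W[obs, , drop = FALSE]
      C <- solve(diag(q) + tau * crossprod(Wo))
      covs[[gi]] <- list(rows = rows, obs = obs, C = C)
      resid <- sweep(y[rows, obs, drop = FALSE], 2L, mu[obs])
      scores[rows, ] <- tau * resid %*% Wo %*% C
    }
    for (gi in seq_along(covs)) {
      info <- covs[[gi]]
      Xg <- scores[info$rows, , drop = FALSE]
      block <- crossprod(Xg) + length(info$rows) * info$C
      for (j in info$obs) SS_by_dim[, , j] <- SS_by_dim[, , j] + block
    }
    # M-step: per-dimension ridge regression with ARD penalty
    for (j in seq_len(d)) {
      ri <- which(!miss[, j])
      if (!length(ri)) next
      Xg <- scores[ri, , drop = FALSE]
      mu[j] <- mean(y[ri, j] - Xg %*% W[j, ])
      A <- SS_by_dim[, , j] + diag(alpha / tau, q, q)
      W[j, ] <- solve(A, crossprod(Xg, y[ri, j] - mu[j]))
    }
    # noise precision over observed cells
    sse <- 0; n_obs <- 0
    for (gi in seq_along(covs)) {
      info <- covs[[gi]]
      rows <- info$rows; obs <- info$obs
      Wo <- W[obs, , drop = FALSE]
      pred <- scores[rows, , drop = FALSE] %*% t(Wo)
      res <- sweep(y[rows, obs, drop = FALSE], 2L, mu[obs]) - pred
      sse <- sse + sum(res^2) + length(rows) * sum(diag(Wo %*% info$C %*% t(Wo)))
      n_obs <- n_obs + length(rows) * length(obs)
    }
    tau <- n_obs / max(sse, 1e-12)
    alpha <- d / (colSums(W^2) + 1e-10)
    theta <- c(W, mu)
    rel <- sqrt(sum((theta - theta_old)^2)) / (sqrt(sum(theta_old^2)) + 1e-12)
    theta_old <- theta
    if (rel < params$tol) { converged <- TRUE; break }
  }
  pred <- scores %*% t(W)
  out <- y
  out[miss] <- sweep(pred, 2L, mu, "+")[miss]
  list(imputed = out,
       diagnostics = list(iterations = iter, converged = converged,
                          n_factors = q,
                          effective_factors = sum(colSums(W^2) > 1e-8)))
}

register_imputer("svd", "Iterative low-rank SVD", "global", FALSE,
                 list(rank = NA_integer_, tol = 1e-4, max_iter = 100L), impute_svd)
register_imputer("bpca", "Bayesian PCA (variational, ARD)", "global", FALSE,
                 list(n_factors = NA_integer_, tol = 1e-4, max_iter = 100L),
                 impute_bpca)
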
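# Internal helpers shared across modules.

#' @importFrom rlang abort warn %||%
NULL

# Round half away from zero (the masking count convention).
round_half_away <- function(x) trunc(x + sign(x) * 0.5)

# Deterministic integer mixing for seed derivation. Keeps every intermediate
# below 2^53 so the arithmetic is exact in doubles, and the result in
# [1, 2^31 - 2] so it is a valid R seed.
mix_seed <- function(...) {
  parts <- list(...)
  h <- 17
  m <- 2147483647 # 2^31 - 1
  for (p in parts) {
    if (is.character(p)) p <- string_code(p)
    for (v in as.numeric(p)) {
      v <- abs(v) %% m
      h <- (h * 69069 + v + 1) %% m
    }
  }
  as.integer(h %% (m - 1)) + 1L
}

# Fold a string to an integer < 2^31 - 1.
string_code <- function(s) {
  h <- 0
  m <- 2147483647
  for (cp in utf8ToInt(paste(s, collapse = "\x1f"))) {
    h <- (h * 131 + cp) %% m
  }
  h
}

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Row means ignoring NA; rows with no observed value fall back to `fallback`.
row_means_obs <- function(x, fallback = 0) {
  m <- rowMeans(x, na.rm = TRUE)
  m[!is.finite(m)] <- fallback
  m
}

is_two_level <- function(g) length(unique(g)) == 2L

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
}
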
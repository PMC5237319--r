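# Step 1 of the simulation procedure: MCAR masking of a complete matrix.

#' Default missing percentages
#'
#' The framework masks each complete matrix at 1%, 3%, 5%, 8% and 10% of all
#' cells.
#'
#' @return Numeric vector `c(0.01, 0.03, 0.05, 0.08, 0.10)`.
#' @export
default_percentages <- function() c(0.01, 0.03, 0.05, 0.08, 0.10)

#' Mask a complete matrix completely at random
#'
#' Exactly `round(percentage * n_cells)` cells (round half away from zero)
#' are drawn uniformly without replacement. Draws are repeated (up to
#' `max_retries`) until every gene keeps at least two observed values and
#' every sample keeps at least one, since distance- and regression-based
#' imputers are undefined on fully missing rows.
#'
#' @param complete A complete [expr_matrix].
#' @param percentage Fraction of all cells to mask, in (0, 0.5].
#' @param seed Integer seed; the mask is deterministic given
#'   `(matrix, percentage, seed)`.
#' @param max_retries Redraw budget for the retention constraint.
#' @return A [mask_matrix] object.
#' @export
make_mask <- function(complete, percentage, seed, max_retries = 1000L) {
  stopifnot(inherits(complete, "expr_matrix"))
  if (!is_complete(complete)) abort("masking requires a complete matrix")
  assert_scalar_number(percentage, "percentage")
  if (percentage <= 0 || percentage > 0.5) {
    abort(sprintf("`percentage` must be in (0, 0.5], got %g", percentage))
  }
  dims <- dim(complete$values)
  n_cells <- prod(dims)
  n_mask <- as.integer(round_half_away(percentage * n_cells))
  if (n_mask < 1L) abort(sprintf("percentage %g masks no cell of a %d x %d matrix",
                                 percentage, dims[1L], dims[2L]))
  if (n_mask > n_cells - 2L * dims[1L]) {
    abort(sprintf("retention constraint unsatisfiable: %d of %d cells on a %d x %d matrix",
                  n_mask, n_cells, dims[1L], dims[2L]))
  }
  mask <- with_seed(seed, {
    found <- NULL
    for (attempt in seq_len(max_retries)) {
      m <- matrix(FALSE, dims[1L], dims[2L])
      m[sample.int(n_cells, n_mask)] <- TRUE
      if (all(rowSums(!m) >= 2L) && all(colSums(!m) >= 1L)) {
        found <- m
        break
      }
    }
    if (is.null(found)) {
      abort(sprintf(
        "could not draw a mask keeping >= 2 observed values per gene on a %d x %d matrix after %d attempts",
        dims[1L], dims[2L], max_retries
      ))
    }
    found
  })
  mask_matrix(complete, mask)
}

#' Generate the five testing matrices of one simulation run
#'
#' One independent MCAR mask per percentage, with per-percentage seeds
#' derived deterministically from `run_seed`, so partial re-runs reproduce
#' individual masks.
#'
#' @param complete A complete [expr_matrix].
#' @param run_seed Integer seed for the run.
#' @param percentages Missing fractions (defaults to [default_percentages()]).
#' @return Named list of [mask_matrix] objects, one per percentage.
#' @export
make_testing_set <- function(complete, run_seed, percentages = default_percentages()) {
  masks <- lapply(seq_along(percentages), function(i) {
    make_mask(complete, percentages[i], seed = mix_seed(run_seed, i))
  })
  names(masks) <- sprintf("%g%%", 100 * percentages)
  masks
}
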
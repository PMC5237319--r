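# Imputation algorithm registry and the uniform `impute()` entry point.
#
# Fourteen built-in algorithms: two naive baselines (zero, row_average), two
# global latent-model methods (svd, bpca) and ten local neighbour/regression
# methods (knn, sknn, iknn, ls, lls, slls, ills and the three shrinkage
# variants of the LLS family). External executables can be registered as
# `plugin:<name>` via [plugin_imputer()].

imputer_registry <- new.env(parent = emptyenv())

register_imputer <- function(id, label, category, baseline, defaults, fn) {
  assign(id, list(id = id, label = label, category = category,
                  baseline = baseline, defaults = defaults, fn = fn),
         envir = imputer_registry)
}

#' List the available imputation algorithms
#'
#' @param include_plugins Also list registered plugin imputers.
#' @return Tibble with columns `algorithm_id`, `label`, `category`
#'   (baseline / global / local / plugin) and `baseline`.
#' @export
list_imputers <- function(include_plugins = TRUE) {
  ids <- ls(imputer_registry)
  entries <- lapply(ids, get, envir = imputer_registry)
  out <- tibble::tibble(
    algorithm_id = vapply(entries, `[[`, character(1), "id"),
    label = vapply(entries, `[[`, character(1), "label"),
    category = vapply(entries, `[[`, character(1), "category"),
    baseline = vapply(entries, `[[`, logical(1), "baseline")
  )
  if (!include_plugins) out <- dplyr::filter(out, .data$category != "plugin")
  # stable, readable order: baselines, global, local, plugins
  ord <- c("baseline", "global", "local", "plugin")
  dplyr::arrange(out, match(.data$category, ord), .data$algorithm_id)
}

imputer_entry <- function(id) {
  if (!exists(id, envir = imputer_registry, inherits = FALSE)) {
    abort(sprintf("unknown imputation algorithm '%s'; see list_imputers()", id))
  }
  get(id, envir = imputer_registry)
}

#' Describe one imputation request
#'
#' @param algorithm Algorithm id from [list_imputers()].
#' @param params Named list of hyperparameter overrides; unknown keys are
#'   rejected.
#' @param seed Integer seed (all built-ins are deterministic; the seed is
#'   part of the contract so stochastic plugins can be reproducible too).
#' @return An `imputer_spec`.
#' @export
imputer_spec <- function(algorithm, params = list(), seed = 1L) {
  entry <- imputer_entry(algorithm)
  bad <- setdiff(names(params), names(entry$defaults))
  if (length(bad)) {
    abort(sprintf("unknown hyperparameter(s) for '%s': %s (known: %s)",
                  algorithm, paste(bad, collapse = ", "),
                  paste(names(entry$defaults), collapse = ", ")))
  }
  structure(list(algorithm_id = algorithm, params = params, seed = as.integer(seed)),
            class = "imputer_spec")
}

#' Impute the missing cells of a masked matrix
#'
#' Dispatches to the requested algorithm, then (independently of the
#' algorithm) overwrites every observed cell with its original value, so
#' observed-cell preservation holds bit-exactly for every method, and checks
#' that no missing value remains.
#'
#' @param masked A [mask_matrix] result.
#' @param algorithm Algorithm id, or an [imputer_spec()].
#' @param params Hyperparameter overrides (ignored when `algorithm` is a
#'   spec).
#' @param seed Seed (ignored when `algorithm` is a spec).
#' @return An [imputation_result].
#' @examples
#' ds <- generate_complete(synthetic_spec(n_genes = 60, seed = 1))
#' mm <- make_mask(ds$matrix, 0.05, seed = 2)
#' res <- impute(mm, "row_average")
#' @export
impute <- function(masked, algorithm, params = list(), seed = 1L) {
  stopifnot(inherits(masked, "masked_matrix"))
  spec <- if (inherits(algorithm, "imputer_spec")) algorithm
          else imputer_spec(algorithm, params, seed)
  entry <- imputer_entry(spec$algorithm_id)
  p <- utils::modifyList(entry$defaults, spec$params)
  p$seed <- spec$seed
  if (n_masked(masked) == 0L) {
    return(imputation_result(spec$algorithm_id, masked$base$values,
                             diagnostics = list(skipped = "no missing cells")))
  }
  out <- entry$fn(masked, p)
  imp <- out$imputed
  if (!identical(dim(imp), dim(masked$mask))) {
    abort(sprintf("'%s' returned a %d x %d matrix for a %d x %d input",
                  spec$algorithm_id, nrow(imp), ncol(imp),
                  nrow(masked$mask), ncol(masked$mask)))
  }
  # observed-cell enforcement
  imp[!masked$mask] <- masked$base$values[!masked$mask]
  if (anyNA(imp[masked$mask])) {
    abort(sprintf("'%s' left %d cells missing", spec$algorithm_id,
                  sum(is.na(imp[masked$mask]))))
  }
  dimnames(imp) <- dimnames(masked$base$values)
  imputation_result(spec$algorithm_id, imp, diagnostics = out$diagnostics %||% list())
}

# ---- baselines --------------------------------------------------------------

impute_zero <- function(masked, params) {
  x <- masked_values(masked)
  x[is.na(x)] <- 0
  list(imputed = x)
}

impute_row_average <- function(masked, params) {
  x <- masked_values(masked)
  empty_rows <- sum(rowSums(!is.na(x)) == 0L) # filled with 0, see row_means_obs
  rm <- row_means_obs(x, fallback = 0)
  idx <- which(is.na(x), arr.ind = TRUE)
  x[idx] <- rm[idx[, 1L]]
  list(imputed = x, diagnostics = list(empty_row_fallbacks = empty_rows))
}

register_imputer("zero", "Zero fill", "baseline", TRUE, list(), impute_zero)
register_imputer("row_average", "Row average", "baseline", TRUE, list(), impute_row_average)
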
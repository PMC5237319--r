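# The simulation engine: for every dataset, run and missing percentage, mask
# the complete matrix, impute with every selected algorithm, and score every
# selected index; each final score S_ij(k) is the mean of the
# |percentages| * B per-run scores.

#' Configure a benchmarking study
#'
#' @param datasets Named list of complete matrices: [expr_matrix] objects,
#'   `mvi_synthetic` objects, or paths readable by [read_expr_matrix()].
#' @param algorithms Character vector of algorithm ids (see
#'   [list_imputers()]) and/or [imputer_spec()] objects.
#' @param indices Subset of `c("inv_nrmse", "cpp", "blci")`.
#' @param scores Comprehensive scores to report, subset of `c("ors", "ons")`.
#' @param B Number of simulation runs per missing percentage.
#' @param percentages Missing fractions (default [default_percentages()]).
#' @param master_seed Single integer from which every mask, imputation and
#'   clustering seed is derived; two studies with the same configuration and
#'   master seed are bit-identical.
#' @param paired Share masks across algorithms within (dataset, run,
#'   percentage) for paired comparison (default); `FALSE` draws independent
#'   masks per algorithm.
#' @param cpp_k,cpp_nstart k-means settings for the CPP index.
#' @param blci_alpha Significance threshold for the BLCI index.
#' @param nrmse_normalization `"sd"` or `"mean"` (see [index_inv_nrmse()]).
#' @return An `eval_config`.
#' @export
eval_config <- function(datasets, algorithms,
                        indices = c("inv_nrmse", "cpp", "blci"),
                        scores = c("ors", "ons"),
                        B = 1L,
                        percentages = default_percentages(),
                        master_seed = 1L,
                        paired = TRUE,
                        cpp_k = 10L, cpp_nstart = 10L,
                        blci_alpha = 0.05,
                        nrmse_normalization = "sd") {
  if (!length(datasets)) abort("select at least one dataset")
  if (is.null(names(datasets)) || any(!nzchar(names(datasets)))) {
    abort("`datasets` must be a named list")
  }
  if (!length(algorithms)) abort("select at least one algorithm")
  indices <- match.arg(indices, index_ids(), several.ok = TRUE)
  scores <- match.arg(scores, c("ors", "ons"), several.ok = TRUE)
  B <- as.integer(B)
  if (B < 1L) abort("`B` must be >= 1")
  for (p in percentages) {
    if (p <= 0 || p > 0.5) abort(sprintf("percentage %g outside (0, 0.5]", p))
  }
  specs <- lapply(algorithms, function(a) {
    if (inherits(a, "imputer_spec")) a else imputer_spec(a)
  })
  ids <- vapply(specs, `[[`, character(1), "algorithm_id")
  if (anyDuplicated(ids)) abort("duplicate algorithm ids in the roster")
  names(specs) <- ids
  structure(
    list(datasets = datasets, algorithms = specs, indices = indices,
         scores = scores, B = B, percentages = percentages,
         master_seed = as.integer(master_seed), paired = paired,
         cpp_k = as.integer(cpp_k), cpp_nstart = as.integer(cpp_nstart),
         blci_alpha = blci_alpha, nrmse_normalization = nrmse_normalization),
    class = "eval_config"
  )
}

resolve_dataset <- function(x, name) {
  m <- if (inherits(x, "expr_matrix")) x
    else if (inherits(x, "mvi_synthetic")) x$matrix
    else if (is.character(x) && length(x) == 1L) read_expr_matrix(x)
    else abort(sprintf("dataset '%s' is neither a matrix nor a file path", name))
  if (!is_complete(m)) {
    abort(sprintf("dataset '%s' contains missing values; the benchmark needs complete matrices", name))
  }
  m
}

#' Run a benchmarking study
#'
#' Executes the four-step simulation procedure: (1) mask each complete matrix
#' completely at random at each configured percentage, (2) impute each masked
#' matrix with each algorithm, (3) score each imputed matrix with each
#' selected index, (4) repeat for `B` runs and average the
#' `|percentages| * B` raw scores into the final per-cell score `S_ij(k)`.
#' Within a (dataset, run, percentage) triple all algorithms receive the
#' identical mask (paired design) unless `paired = FALSE`, and each imputed
#' matrix is scored once per index (imputations are never repeated per
#' index). An algorithm failing on one mask marks only its own cells failed.
#'
#' @param config An [eval_config()].
#' @param verbose Print per-cell progress.
#' @return An `mvi_study` with elements `raw` (tibble: dataset, algorithm,
#'   index, run, percentage, score, failed, error), `summary` (tibble:
#'   index, dataset, algorithm, S, n_raw), `manifest` (per-mask seeds and
#'   checksums) and `config`.
#' @export
evaluate_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "eval_config"))
  mats <- lapply(names(config$datasets),
                 function(nm) resolve_dataset(config$datasets[[nm]], nm))
  names(mats) <- names(config$datasets)

  raw <- list()
  manifest <- list()
  for (ds_name in names(mats)) {
    complete <- mats[[ds_name]]
    cpp_cache <- NULL
    cfg_idx <- list(nrmse_normalization = config$nrmse_normalization,
                    cpp_k = config$cpp_k, cpp_nstart = config$cpp_nstart,
                    cpp_seed = mix_seed(config$master_seed, "cpp", ds_name),
                    blci_alpha = config$blci_alpha)
    if ("cpp" %in% config$indices) {
      cpp_cache <- cluster_genes(complete$values, cfg_idx$cpp_k,
                                 seed = cfg_idx$cpp_seed, nstart = cfg_idx$cpp_nstart)
    }
    for (b in seq_len(config$B)) {
      for (pi in seq_along(config$percentages)) {
        pct <- config$percentages[pi]
        shared_mask <- NULL
        if (config$paired) {
          mseed <- mix_seed(config$master_seed, "mask", ds_name, b, pi)
          shared_mask <- make_mask(complete, pct, seed = mseed)
          manifest[[length(manifest) + 1L]] <- tibble::tibble(
            dataset = ds_name, run = b, percentage = pct, seed = mseed,
            checksum = mask_checksum(shared_mask)
          )
        }
        for (spec in config$algorithms) {
          algo <- spec$algorithm_id
          masked <- shared_mask
          if (is.null(masked)) {
            mseed <- mix_seed(config$master_seed, "mask", ds_name, b, pi, algo)
            masked <- make_mask(complete, pct, seed = mseed)
            manifest[[length(manifest) + 1L]] <- tibble::tibble(
              dataset = ds_name, run = b, percentage = pct, seed = mseed,
              checksum = mask_checksum(masked), algorithm = algo
            )
          }
          run_spec <- imputer_spec(algo, spec$params,
                                   seed = mix_seed(config$master_seed, "impute",
                                                   ds_name, b, pi, algo))
          scores <- run_and_score(complete, masked, run_spec, config$indices,
                                  cfg_idx, cpp_cache)
          if (verbose) {
            message(sprintf("[%s] run %d, %g%%, %s: %s", ds_name, b, 100 * pct, algo,
                            paste(sprintf("%s=%.4g", names(scores$values), scores$values),
                                  collapse = " ")))
          }
          raw[[length(raw) + 1L]] <- tibble::tibble(
            dataset = ds_name, algorithm = algo, index = config$indices,
            run = b, percentage = pct,
            score = scores$values[config$indices],
            failed = scores$failed, error = scores$error
          )
        }
      }
    }
  }
  raw <- dplyr::bind_rows(raw)
  summary <- raw |>
    dplyr::group_by(.data$index, .data$dataset, .data$algorithm) |>
    dplyr::summarise(
      S = if (any(.data$failed)) NA_real_ else mean(.data$score),
      n_raw = sum(!.data$failed),
      .groups = "drop"
    )
  if (any(raw$failed)) {
    warn(sprintf("%d raw score(s) failed; the affected cells are excluded from ORS/ONS",
                 sum(raw$failed)))
  }
  structure(
    list(raw = raw, summary = summary,
         manifest = dplyr::bind_rows(manifest),
         config = config),
    class = "mvi_study"
  )
}

run_and_score <- function(complete, masked, spec, indices, cfg_idx, cpp_cache) {
  values <- stats::setNames(rep(NA_real_, length(indices)), indices)
  result <- tryCatch(impute(masked, spec), error = function(e) e)
  if (inherits(result, "error")) {
    return(list(values = values, failed = rep(TRUE, length(indices)),
                error = rep(conditionMessage(result), length(indices))))
  }
  failed <- logical(length(indices))
  errs <- rep(NA_character_, length(indices))
  for (i in seq_along(indices)) {
    sc <- tryCatch(
      score_index(indices[i], complete, result, masked, cfg_idx,
                  cache = if (indices[i] == "cpp") cpp_cache),
      error = function(e) e
    )
    if (inherits(sc, "error")) {
      failed[i] <- TRUE
      errs[i] <- conditionMessage(sc)
    } else {
      values[i] <- sc$value
    }
  }
  list(values = values, failed = failed, error = errs)
}

mask_checksum <- function(masked) mix_seed("mask-checksum", which(masked$mask))

#' Evaluate a single (dataset, algorithm, index) cell
#'
#' Convenience wrapper around the engine for one cell: returns the final
#' score (the mean of the `|percentages| * B` raw scores) and the raw scores
#' themselves.
#'
#' @param complete A complete [expr_matrix].
#' @param algorithm Algorithm id or [imputer_spec()].
#' @param index One of `"inv_nrmse"`, `"cpp"`, `"blci"`.
#' @param dataset_id Dataset name used in seed derivation, so a cell
#'   evaluated alone matches the same cell inside a full study.
#' @inheritParams eval_config
#' @param ... Passed on to [eval_config()].
#' @return List with `S` (scalar) and `raw` (tibble of per-run scores).
#' @export
evaluate_cell <- function(complete, algorithm, index, B = 1L,
                          percentages = default_percentages(),
                          master_seed = 1L, dataset_id = "dataset", ...) {
  ds <- stats::setNames(list(complete), dataset_id)
  cfg <- eval_config(ds, list(algorithm), indices = index, B = B,
                     percentages = percentages, master_seed = master_seed, ...)
  study <- evaluate_study(cfg)
  list(S = study$summary$S[[1L]], raw = study$raw)
}

#' @export
print.mvi_study <- function(x, ...) {
  cat(sprintf(
    "<mvi_study> %d dataset(s) x %d algorithm(s) x %d index(es); B = %d, %d percentages; %d raw scores (%d failed)\n",
    length(unique(x$raw$dataset)), length(unique(x$raw$algorithm)),
    length(unique(x$raw$index)), x$config$B, length(x$config$percentages),
    nrow(x$raw), sum(x$raw$failed)
  ))
  invisible(x)
}
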
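# External-executable imputer plugins.
#
# Contract: the executable is called with two extra arguments, the path of a
# TSV matrix containing "NA" at missing cells and the path where it must
# write a complete matrix with the same gene/sample identifiers. Observed
# cells may not move by more than 1e-9 and no missing cell may remain.

#' Declare an external imputation plugin
#'
#' @param name Short plugin name; the algorithm id becomes `plugin:<name>`.
#' @param executable Path to the executable.
#' @param args Extra arguments placed before the input/output paths.
#' @param timeout Timeout in seconds (default one hour).
#' @return A `plugin_contract`.
#' @export
plugin_imputer <- function(name, executable, args = character(0), timeout = 3600) {
  if (!nzchar(name) || grepl("[^A-Za-z0-9_.-]", name)) {
    abort("plugin name must be non-empty and use only [A-Za-z0-9_.-]")
  }
  structure(
    list(name = name, executable = executable, args = as.character(args),
         timeout = timeout),
    class = "plugin_contract"
  )
}

#' Register a plugin in the algorithm registry
#'
#' After registration the plugin can be used anywhere a built-in id is
#' accepted (e.g. in [eval_config()]), under the id `plugin:<name>`.
#'
#' @param contract A [plugin_imputer()] contract.
#' @return The algorithm id, invisibly.
#' @export
register_plugin <- function(contract) {
  stopifnot(inherits(contract, "plugin_contract"))
  id <- paste0("plugin:", contract$name)
  register_imputer(id, paste0("Plugin '", contract$name, "'"), "plugin", FALSE,
                   list(), function(masked, params) run_plugin_raw(contract, masked))
  invisible(id)
}

run_plugin_raw <- function(contract, masked) {
  if (!file.exists(contract$executable)) {
    abort(sprintf("plugin '%s': executable not found: %s",
                  contract$name, contract$executable))
  }
  dir <- tempfile("mvibench_plugin_")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  in_path <- file.path(dir, "input.tsv")
  out_path <- file.path(dir, "output.tsv")
  err_path <- file.path(dir, "stderr.txt")
  write_expr_matrix(masked, in_path)
  status <- suppressWarnings(system2(
    contract$executable, c(contract$args, in_path, out_path),
    stdout = FALSE, stderr = err_path, timeout = contract$timeout
  ))
  if (!identical(status, 0L)) {
    err <- if (file.exists(err_path)) paste(readLines(err_path, warn = FALSE), collapse = "\n") else ""
    abort(sprintf("plugin '%s' exited with status %s\n%s", contract$name, status, err))
  }
  if (!file.exists(out_path)) {
    abort(sprintf("plugin '%s' wrote no output file", contract$name))
  }
  out <- read_expr_matrix(out_path)
  validate_plugin_output(contract, masked, out$values)
  list(imputed = out$values, diagnostics = list(plugin = contract$name))
}

validate_plugin_output <- function(contract, masked, imp) {
  base <- masked$base$values
  if (!identical(dim(imp), dim(base)) ||
      !identical(rownames(imp), rownames(base)) ||
      !identical(colnames(imp), colnames(base))) {
    abort(sprintf("plugin '%s': output shape or identifiers do not match the input",
                  contract$name))
  }
  if (anyNA(imp)) {
    abort(sprintf("plugin '%s': %d missing cells remain in the output",
                  contract$name, sum(is.na(imp))))
  }
  obs <- !masked$mask
  drift <- max(abs(imp[obs] - base[obs]))
  if (drift > 1e-9) {
    abort(sprintf("plugin '%s': observed cells altered by up to %g (tolerance 1e-9)",
                  contract$name, drift))
  }
  invisible(TRUE)
}

#' Run a plugin directly on a masked matrix
#'
#' @param masked A [mask_matrix] result.
#' @param contract A [plugin_imputer()] contract.
#' @return An [imputation_result] with `algorithm_id = "plugin:<name>"`.
#' @export
run_plugin <- function(masked, contract) {
  stopifnot(inherits(masked, "masked_matrix"), inherits(contract, "plugin_contract"))
  out <- run_plugin_raw(contract, masked)
  imp <- out$imputed
  imp[!masked$mask] <- masked$base$values[!masked$mask]
  imputation_result(paste0("plugin:", contract$name), imp, out$diagnostics)
}
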
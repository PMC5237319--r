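# YAML study configuration for the command-line interface.
#
# Example:
#   datasets:
#     liver: liver_matrix.tsv
#     yeast: {matrix: yeast_matrix.tsv, groups: yeast_groups.tsv}
#   algorithms: [zero, row_average, knn, lls]
#   imputers:
#     knn: {k: 15}
#   plugins:
#     - {name: mymethod, executable: ./my_imputer.R, timeout: 600}
#   indices: [inv_nrmse, cpp, blci]
#   scores: [ors, ons]
#   B: 25
#   percentages: [0.01, 0.03, 0.05, 0.08, 0.10]
#   master_seed: 1
#   paired: true
#   index_params:
#     cpp: {k: 10, nstart: 10}
#     blci: {alpha: 0.05}
#     nrmse: {normalization: sd}

#' Load a study configuration from a YAML file
#'
#' Reads dataset paths (with optional group-label sidecars), the algorithm
#' roster with per-algorithm hyperparameter overrides under `imputers.<id>`,
#' plugin declarations, index hyperparameters under `index_params`, and the
#' study settings (`indices`, `scores`, `B`, `percentages`, `master_seed`,
#' `paired`). Plugins named in the file are registered as a side effect.
#'
#' @param path YAML file path.
#' @param base_dir Directory against which relative dataset/plugin paths are
#'   resolved (defaults to the YAML file's directory).
#' @return An [eval_config()].
#' @export
load_eval_config <- function(path, base_dir = dirname(path)) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  rel <- function(p) if (grepl("^(/|~)", p)) p else file.path(base_dir, p)

  if (is.null(cfg$datasets) || !length(cfg$datasets)) abort("config: `datasets` is required")
  datasets <- lapply(names(cfg$datasets), function(nm) {
    d <- cfg$datasets[[nm]]
    if (is.character(d)) return(read_expr_matrix(rel(d)))
    read_expr_matrix(rel(d$matrix),
                     groups = if (!is.null(d$groups)) read_group_labels(rel(d$groups)))
  })
  names(datasets) <- names(cfg$datasets)

  for (pl in cfg$plugins %||% list()) {
    register_plugin(plugin_imputer(pl$name, rel(pl$executable),
                                   args = pl$args %||% character(0),
                                   timeout = pl$timeout %||% 3600))
  }

  algo_ids <- unlist(cfg$algorithms %||% list_imputers(include_plugins = FALSE)$algorithm_id)
  overrides <- cfg$imputers %||% list()
  algorithms <- lapply(algo_ids, function(id) {
    imputer_spec(id, params = overrides[[id]] %||% list())
  })

  ip <- cfg$index_params %||% list()
  eval_config(
    datasets = datasets,
    algorithms = algorithms,
    indices = unlist(cfg$indices %||% index_ids()),
    scores = unlist(cfg$scores %||% c("ors", "ons")),
    B = cfg$B %||% 1L,
    percentages = unlist(cfg$percentages %||% default_percentages()),
    master_seed = cfg$master_seed %||% 1L,
    paired = cfg$paired %||% TRUE,
    cpp_k = ip$cpp$k %||% 10L,
    cpp_nstart = ip$cpp$nstart %||% 10L,
    blci_alpha = ip$blci$alpha %||% 0.05,
    nrmse_normalization = ip$nrmse$normalization %||% "sd"
  )
}

#' Write the long-format raw scores and the score table as TSV
#'
#' @param study An `mvi_study`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "mvi_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(raw = file.path(dir, "raw_scores.tsv"),
             summary = file.path(dir, "score_table.tsv"))
  utils::write.table(study$raw, paths[["raw"]], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$summary, paths[["summary"]], sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a saved score table back for re-reporting
#'
#' @param path A `score_table.tsv` written by [write_study()].
#' @return Tibble usable by [compute_ors()] / [compute_ons()].
#' @export
read_score_table <- function(path) {
  tab <- utils::read.delim(path, colClasses = c("character", "character", "character",
                                                "numeric", "integer"))
  tibble::as_tibble(tab)
}
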
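# Comprehensive performance scores across (index, dataset) cells.
#
# ORS: within every cell, algorithms are ranked by descending score (rank 1 =
# best, fractional ranks on ties); an algorithm's ORS is the sum of its ranks
# over all cells -- smaller is better.
#
# ONS: within every cell, scores are divided by the cell's best score,
# N_ij(k) = S_ij(k) / max_k' S_ij(k'); an algorithm's ONS is the sum of its
# normalized scores -- larger is better, with maximum I * J. BLCI values can
# be negative, so for ONS only they are affinely mapped onto [0, 1] via
# (value + 1) / 2 before normalization; the mapping is recorded in the
# result.

summary_of <- function(x) {
  if (inherits(x, "mvi_study")) return(x$summary)
  if (is.data.frame(x)) {
    need <- c("index", "dataset", "algorithm", "S")
    if (!all(need %in% names(x))) {
      abort(paste0("expected columns: ", paste(need, collapse = ", ")))
    }
    return(tibble::as_tibble(x))
  }
  abort("`x` must be an mvi_study or a summary data frame")
}

drop_failed_cells <- function(summ) {
  failed <- is.na(summ$S)
  if (any(failed)) {
    warn(sprintf("dropping %d failed (index, dataset, algorithm) cells from the aggregation",
                 sum(failed)))
  }
  out <- summ[!failed, , drop = FALSE]
  # cells where every algorithm failed disappear entirely
  out
}

#' Overall ranking score (ORS)
#'
#' @param x An `mvi_study` or a data frame with columns `index`, `dataset`,
#'   `algorithm`, `S` (`NA` marks a failed cell).
#' @return Tibble with one row per algorithm: `ors` (sum of within-cell
#'   ranks, smaller is better), `n_cells` evaluated, and `mean_rank`; sorted
#'   ascending by `ors`. The per-cell ranks are attached as attribute
#'   `"ranks"`.
#' @export
compute_ors <- function(x) {
  summ <- drop_failed_cells(summary_of(x))
  if (!nrow(summ)) abort("no evaluated cells to rank")
  ranks <- summ |>
    dplyr::group_by(.data$index, .data$dataset) |>
    dplyr::mutate(rank = rank(-.data$S, ties.method = "average")) |>
    dplyr::ungroup()
  out <- ranks |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(ors = sum(.data$rank), n_cells = dplyr::n(),
                     mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(.data$ors)
  attr(out, "ranks") <- ranks
  out
}

#' Overall normalized score (ONS)
#'
#' @inheritParams compute_ors
#' @param blci_rescale Map BLCI scores from [-1, 1] to [0, 1] via
#'   `(value + 1) / 2` before normalization (default `TRUE`; the per-cell
#'   ratio assumes nonnegative scores).
#' @return Tibble with one row per algorithm: `ons` (sum of normalized
#'   scores, larger is better, maximum = number of cells) and `n_cells`;
#'   sorted descending by `ons`. Per-cell normalized scores `N` are attached
#'   as attribute `"normalized"`.
#' @export
compute_ons <- function(x, blci_rescale = TRUE) {
  summ <- drop_failed_cells(summary_of(x))
  if (!nrow(summ)) abort("no evaluated cells to normalize")
  summ <- dplyr::mutate(
    summ,
    S_adj = dplyr::if_else(blci_rescale & .data$index == "blci",
                           (.data$S + 1) / 2, .data$S)
  )
  norm <- summ |>
    dplyr::group_by(.data$index, .data$dataset) |>
    dplyr::mutate(cell_max = max(.data$S_adj)) |>
    dplyr::ungroup()
  bad <- norm$cell_max <= 0
  if (any(bad)) {
    cell <- norm[bad, c("index", "dataset")][1L, ]
    abort(sprintf("ONS undefined: non-positive best score in cell (%s, %s)",
                  cell$index, cell$dataset))
  }
  norm <- dplyr::mutate(norm, N = .data$S_adj / .data$cell_max)
  out <- norm |>
    dplyr::group_by(.data$algorithm) |>
    dplyr::summarise(ons = sum(.data$N), n_cells = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$ons))
  attr(out, "normalized") <- norm
  attr(out, "blci_rescale") <- blci_rescale
  out
}

#' Render a study's comparison report to disk
#'
#' Writes `overall_ors.tsv` / `overall_ons.tsv` (as selected), one
#' `detail_<index>_<dataset>.tsv` per in-scope cell with scores and ranks,
#' and `summary.json` (scores, normalized scores, ranks, configuration echo).
#' Scope filters restrict the report to index/dataset subsets without
#' recomputation.
#'
#' @param study An `mvi_study`.
#' @param dir Output directory (created if needed).
#' @param scores Which comprehensive scores to render.
#' @param indices,datasets Optional scope filters (character vectors).
#' @param figures Also write bar-chart figures (PNG) per comprehensive score.
#' @return Named character vector of the files written, invisibly.
#' @export
render_report <- function(study, dir, scores = study$config$scores,
                          indices = NULL, datasets = NULL, figures = FALSE) {
  stopifnot(inherits(study, "mvi_study"))
  summ <- study$summary
  if (!is.null(indices)) summ <- dplyr::filter(summ, .data$index %in% indices)
  if (!is.null(datasets)) summ <- dplyr::filter(summ, .data$dataset %in% datasets)
  if (!nrow(summ)) abort("empty report scope: no (index, dataset) cells selected")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tsv <- function(d, name) {
    p <- file.path(dir, name)
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE)
    written[[name]] <<- p
  }

  ors <- if ("ors" %in% scores) compute_ors(summ)
  ons <- if ("ons" %in% scores) compute_ons(summ)
  if (!is.null(ors)) tsv(ors, "overall_ors.tsv")
  if (!is.null(ons)) tsv(ons, "overall_ons.tsv")

  ranks <- attr(compute_ors(summ), "ranks")
  cells <- dplyr::distinct(summ, .data$index, .data$dataset)
  for (r in seq_len(nrow(cells))) {
    d <- ranks |>
      dplyr::filter(.data$index == cells$index[r], .data$dataset == cells$dataset[r]) |>
      dplyr::arrange(.data$rank)
    tsv(d, sprintf("detail_%s_%s.tsv", cells$index[r], cells$dataset[r]))
  }

  meta <- list(
    scores = as.list(stats::setNames(
      list(if (!is.null(ors)) ors else NULL, if (!is.null(ons)) ons else NULL),
      c("ors", "ons")
    )),
    ranks = ranks,
    blci_ons_mapping = "(value + 1) / 2 before per-cell normalization",
    config = list(
      datasets = names(study$config$datasets),
      algorithms = names(study$config$algorithms),
      indices = study$config$indices,
      percentages = study$config$percentages,
      B = study$config$B,
      master_seed = study$config$master_seed,
      paired = study$config$paired
    ),
    mask_manifest = study$manifest
  )
  p <- file.path(dir, "summary.json")
  jsonlite::write_json(meta, p, auto_unbox = TRUE, digits = NA, null = "null")
  written[["summary.json"]] <- p

  if (figures) {
    for (sc in scores) {
      fig <- autoplot_overall(if (sc == "ors") ors else ons, sc)
      fp <- file.path(dir, sprintf("overall_%s.png", sc))
      ggplot2::ggsave(fp, fig, width = 7, height = 4.5, dpi = 150)
      written[[basename(fp)]] <- fp
    }
  }
  invisible(written)
}

autoplot_overall <- function(tab, score) {
  col <- score
  ggplot2::ggplot(tab, ggplot2::aes(
    x = stats::reorder(.data$algorithm, if (score == "ors") -.data$ors else .data$ons),
    y = .data[[col]]
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(
      x = NULL, y = toupper(score),
      title = sprintf("Overall %s score (%s is better)",
                      toupper(score), if (score == "ors") "smaller" else "larger")
    ) +
    ggplot2::theme_minimal()
}
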
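# broom-style accessors and ggplot2 autoplot methods.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a benchmarking study
#'
#' @param x An `mvi_study`.
#' @param type `"summary"` (one row per index x dataset x algorithm cell,
#'   default) or `"raw"` (one row per simulation run and percentage).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mvi_study
#' @export
tidy.mvi_study <- function(x, type = c("summary", "raw"), ...) {
  type <- match.arg(type)
  if (type == "raw") x$raw else x$summary
}

#' @rdname tidy.mvi_study
#' @method glance mvi_study
#' @export
glance.mvi_study <- function(x, ...) {
  tibble::tibble(
    n_datasets = length(unique(x$raw$dataset)),
    n_algorithms = length(unique(x$raw$algorithm)),
    n_indices = length(unique(x$raw$index)),
    n_percentages = length(x$config$percentages),
    B = x$config$B,
    n_raw_scores = nrow(x$raw),
    n_failed = sum(x$raw$failed),
    paired = x$config$paired,
    master_seed = x$config$master_seed
  )
}

#' Plot the per-cell scores of a study
#'
#' Bar chart of the final score S of every algorithm, faceted by index and
#' dataset (free scales: the three indices live on different ranges).
#'
#' @param object An `mvi_study`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mvi_study
#' @export
autoplot.mvi_study <- function(object, ...) {
  d <- dplyr::filter(object$summary, !is.na(.data$S))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$algorithm, y = .data$S)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_grid(index ~ dataset, scales = "free_y") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "final score S (mean of per-run scores)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot raw index scores against the missing percentage
#'
#' Shows how each algorithm's per-run scores degrade as the missing fraction
#' grows; one line per algorithm, faceted by index and dataset.
#'
#' @param study An `mvi_study`.
#' @param index Optional single index to show.
#' @return A ggplot object.
#' @export
plot_degradation <- function(study, index = NULL) {
  d <- dplyr::filter(study$raw, !.data$failed)
  if (!is.null(index)) d <- dplyr::filter(d, .data$index == !!index)
  d <- d |>
    dplyr::group_by(.data$dataset, .data$algorithm, .data$index, .data$percentage) |>
    dplyr::summarise(score = mean(.data$score), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$percentage, y = .data$score,
                                  colour = .data$algorithm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(index ~ dataset, scales = "free_y") +
    ggplot2::scale_x_continuous(labels = function(p) paste0(100 * p, "%")) +
    ggplot2::labs(x = "missing percentage", y = "mean per-run score") +
    ggplot2::theme_minimal()
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`

#' @importFrom rlang .data
NULL
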
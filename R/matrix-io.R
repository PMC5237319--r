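# Reading and writing expression matrices as plain TSV.
#
# Format: tab-separated, UTF-8, LF endings; first header cell is "gene_id",
# remaining header cells are sample identifiers; one row per gene. Missing
# values are written as "NA" and accepted on input as "NA", "NaN" or an
# empty field (case-insensitive) -- GEO-derived flat files use these
# interchangeably.

#' Read an expression matrix from a delimited text file
#'
#' @param path Path to a delimited file: first column gene identifiers,
#'   first row sample identifiers.
#' @param sep Field separator (tab by default).
#' @param missing_tokens Strings treated as missing on input
#'   (case-insensitive); missing values are always written back as `"NA"`.
#' @param groups Optional path to a sidecar two-column TSV (`sample_id`,
#'   `group`) with a two-level sample assignment, or a vector accepted by
#'   [expr_matrix()].
#' @return A validated [expr_matrix].
#' @export
read_expr_matrix <- function(path, sep = "\t", missing_tokens = c("NA", "NaN", ""),
                             groups = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) | seq_along(lines) == 1L]
  if (length(lines) < 2L) abort(sprintf("%s: need a header line and at least one gene row", path))
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  if (n_col < 2L) abort(sprintf("%s: header must name at least one sample", path))
  samples <- header[-1L]
  if (anyDuplicated(samples)) {
    abort(sprintf("%s: duplicate sample identifiers in header", path))
  }
  body <- fields[-1L]
  widths <- lengths(body)
  # a trailing missing field after the last separator is dropped by strsplit
  short <- widths == n_col - 1L
  if (any(short)) {
    body[short] <- lapply(body[short], function(f) c(f, ""))
    widths[short] <- n_col
  }
  if (any(widths != n_col)) {
    bad <- which(widths != n_col)[1L]
    abort(sprintf("%s: row %d has %d fields, expected %d (ragged file)",
                  path, bad + 1L, widths[bad], n_col))
  }
  genes <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(genes)) {
    abort(sprintf("%s: duplicate gene identifiers (e.g. '%s')",
                  path, genes[duplicated(genes)][1L]))
  }
  raw <- t(vapply(body, function(f) f[-1L], character(n_col - 1L)))
  if (ncol(raw) != n_col - 1L) raw <- matrix(raw, ncol = n_col - 1L)
  token <- trimws(raw)
  is_missing <- tolower(token) %in% tolower(missing_tokens)
  vals <- suppressWarnings(as.numeric(token))
  bad <- which(!is_missing & is.na(vals))
  if (length(bad)) {
    ij <- arrayInd(bad[1L], dim(token))
    abort(sprintf("%s: non-numeric value '%s' at gene '%s', sample '%s'",
                  path, token[bad[1L]], genes[ij[1L]], samples[ij[2L]]))
  }
  vals[is_missing] <- NA_real_
  m <- matrix(vals, nrow = length(genes), dimnames = list(genes, samples))
  if (any(is.infinite(m))) abort(sprintf("%s: infinite value encountered", path))
  if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    groups <- read_group_labels(groups)
  }
  expr_matrix(m, groups = groups)
}

#' Read a sidecar group-label file
#'
#' Two tab-separated columns, `sample_id` and `group`, with or without a
#' header line.
#'
#' @param path File path.
#' @return Named character vector of group labels keyed by sample id.
#' @export
read_group_labels <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- utils::read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) abort(sprintf("%s: expected two columns (sample_id, group)", path))
  if (identical(tolower(tab[1L, 1L]), "sample_id")) tab <- tab[-1L, , drop = FALSE]
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Write an expression matrix, masked matrix or imputation result as TSV
#'
#' Output is tab-separated with header cell `gene_id`, `NA` for missing
#' values, UTF-8 and LF line endings; `read_expr_matrix()` round-trips it.
#'
#' @param x An [expr_matrix], [mask_matrix] result, [imputation_result], or
#'   plain matrix.
#' @param path Output file path.
#' @param digits Significant digits used for formatting (default keeps full
#'   double precision).
#' @return `path`, invisibly.
#' @export
write_expr_matrix <- function(x, path, digits = 17L) {
  v <- if (inherits(x, "expr_matrix")) x$values
    else if (inherits(x, "masked_matrix")) masked_values(x)
    else if (inherits(x, "imputation_result")) x$imputed
    else if (is.matrix(x)) x
    else abort("don't know how to write this object as an expression matrix")
  if (nrow(v) < 1L || ncol(v) < 1L) abort("refusing to write an empty matrix")
  if (is.null(rownames(v)) || is.null(colnames(v))) abort("matrix must carry gene and sample identifiers")
  txt <- format(v, digits = digits, trim = TRUE, scientific = NA)
  txt[is.na(v)] <- "NA"
  lines <- c(
    paste(c("gene_id", colnames(v)), collapse = "\t"),
    paste(rownames(v), apply(txt, 1L, paste, collapse = "\t"), sep = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname write_expr_matrix
#' @export
write_group_labels <- function(x, path) {
  g <- if (inherits(x, "expr_matrix")) x$groups else x
  if (is.null(g)) abort("no group labels to write")
  lines <- c("sample_id\tgroup", paste(names(g), g, sep = "\t"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Export the coordinates of masked cells for audit
#'
#' @param masked A [mask_matrix] result.
#' @param path Optional output TSV path; when `NULL` the tibble is returned
#'   only.
#' @return Tibble with columns `gene_id` and `sample_id`, one row per masked
#'   cell, in column-major order.
#' @export
mask_pairs <- function(masked, path = NULL) {
  stopifnot(inherits(masked, "masked_matrix"))
  idx <- which(masked$mask)
  ij <- arrayInd(idx, dim(masked$mask))
  out <- tibble::tibble(
    gene_id = rownames(masked$mask)[ij[, 1L]],
    sample_id = colnames(masked$mask)[ij[, 2L]]
  )
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
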
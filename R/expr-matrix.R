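#' Expression matrix container
#'
#' An `expr_matrix` holds a genes x samples matrix of (log-scale) expression
#' values with unique gene and sample identifiers and, optionally, a
#' two-level group assignment of the samples used for differential-expression
#' concordance scoring.
#'
#' @param values Numeric matrix (genes in rows, samples in columns). Row and
#'   column names are used as gene and sample identifiers; if absent,
#'   `gene_1..n` / `sample_1..m` are generated.
#' @param groups Optional two-level sample grouping: a character or factor
#'   vector of length `ncol(values)`, or a named vector whose names are
#'   sample identifiers.
#' @return An object of class `expr_matrix` with elements `values` and
#'   `groups`.
#' @examples
#' m <- expr_matrix(matrix(rnorm(12), 3, 4))
#' is_complete(m)
#' @export
expr_matrix <- function(values, groups = NULL) {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L || ncol(values) < 1L) {
    abort("an expression matrix needs at least one gene and one sample")
  }
  if (is.null(rownames(values))) rownames(values) <- paste0("gene_", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- paste0("sample_", seq_len(ncol(values)))
  if (anyDuplicated(rownames(values))) abort("duplicate gene identifiers")
  if (anyDuplicated(colnames(values))) abort("duplicate sample identifiers")
  if (any(is.infinite(values))) abort("expression values must be finite or missing (NA)")
  if (!is.null(groups)) {
    groups <- as.character(groups)
    if (!is.null(names(groups))) {
      missing_ids <- setdiff(colnames(values), names(groups))
      if (length(missing_ids)) {
        abort(paste0("group labels missing for samples: ", paste(missing_ids, collapse = ", ")))
      }
      groups <- groups[colnames(values)]
    } else if (length(groups) != ncol(values)) {
      abort("`groups` must have one label per sample")
    }
    if (!is_two_level(groups)) abort("`groups` must have exactly two levels")
    names(groups) <- colnames(values)
  }
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @rdname expr_matrix
#' @param x Object to coerce or query.
#' @export
as_expr_matrix <- function(x, groups = NULL) {
  if (inherits(x, "expr_matrix")) {
    if (!is.null(groups)) x <- expr_matrix(x$values, groups)
    return(x)
  }
  expr_matrix(x, groups)
}

#' @rdname expr_matrix
#' @export
is_complete <- function(x) {
  stopifnot(inherits(x, "expr_matrix"))
  !anyNA(x$values)
}

#' @rdname expr_matrix
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expr_matrix
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d genes x %d samples; %s; groups: %s\n",
    nrow(x$values), ncol(x$values),
    if (is_complete(x)) "complete" else sprintf("%d missing cells", sum(is.na(x$values))),
    if (is.null(x$groups)) "none" else paste(unique(x$groups), collapse = " / ")
  ))
  invisible(x)
}

#' Masked expression matrix
#'
#' Pairs a complete [expr_matrix] with a logical missingness mask (`TRUE` =
#' held out). The masked view of the values, with `NA` at masked cells, is
#' obtained with [masked_values()].
#'
#' @param complete A complete `expr_matrix`.
#' @param mask Logical matrix of the same shape; `TRUE` marks masked cells.
#' @param check_retention Enforce that every gene keeps at least two observed
#'   values and every sample at least one (the default for simulation-grade
#'   masks; disable for exhaustive small-matrix enumeration).
#' @return Object of class `masked_matrix` with elements `base`, `mask` and
#'   `percentage` (realized masked fraction).
#' @export
mask_matrix <- function(complete, mask, check_retention = TRUE) {
  stopifnot(inherits(complete, "expr_matrix"))
  if (!is_complete(complete)) abort("masking requires a complete matrix")
  if (!is.logical(mask) || !identical(dim(mask), dim(complete$values))) {
    abort("`mask` must be a logical matrix with the same shape as the data")
  }
  if (check_retention) {
    if (any(rowSums(!mask) < 2L)) abort("every gene must retain >= 2 observed values")
    if (any(colSums(!mask) < 1L)) abort("every sample must retain >= 1 observed value")
  }
  dimnames(mask) <- dimnames(complete$values)
  structure(
    list(base = complete, mask = mask, percentage = mean(mask)),
    class = "masked_matrix"
  )
}

#' @rdname mask_matrix
#' @param x A `masked_matrix`.
#' @export
masked_values <- function(x) {
  stopifnot(inherits(x, "masked_matrix"))
  v <- x$base$values
  v[x$mask] <- NA_real_
  v
}

#' @rdname mask_matrix
#' @export
n_masked <- function(x) sum(x$mask)

#' @export
print.masked_matrix <- function(x, ...) {
  cat(sprintf(
    "<masked_matrix> %d genes x %d samples; %d masked cells (%.2f%%)\n",
    nrow(x$base$values), ncol(x$base$values), sum(x$mask), 100 * mean(x$mask)
  ))
  invisible(x)
}

#' Imputation result container
#'
#' @param algorithm_id Identifier of the algorithm that produced the matrix.
#' @param imputed Numeric matrix of the same shape as the masked input with
#'   no remaining missing values.
#' @param diagnostics Named list of per-run metadata (iteration counts,
#'   fallback counts, convergence flags).
#' @return Object of class `imputation_result`.
#' @export
imputation_result <- function(algorithm_id, imputed, diagnostics = list()) {
  if (anyNA(imputed)) abort("an imputation result may not contain missing values")
  structure(
    list(algorithm_id = algorithm_id, imputed = imputed, diagnostics = diagnostics),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf(
    "<imputation_result> %s: %d x %d matrix\n",
    x$algorithm_id, nrow(x$imputed), ncol(x$imputed)
  ))
  invisible(x)
}
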
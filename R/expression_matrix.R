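#' Isoform-by-experiment expression matrix
#'
#' Container for isoform-level expression values. Rows are isoforms
#' (instances), columns are experiments (features of the instance vectors).
#' The matrix carries an explicit `space` flag so that downstream operations
#' can enforce their preconditions: `"fpkm"` for raw quantifier output
#' (non-negative, `NA` = missing) and `"log2"` for the transformed working
#' space in which every cell is finite and missing values equal the
#' `sentinel` exactly (default -15).
#'
#' @param values numeric matrix with unique isoform row names and unique
#'   experiment column names.
#' @param space `"fpkm"` or `"log2"`.
#' @param sentinel value standing in for missing/unobserved expression in
#'   log2 space.
#' @return An object of class `expression_matrix`: a list with elements
#'   `values`, `space`, `sentinel`.
#' @examples
#' m <- matrix(c(1, 8, 0, 2), 2, 2,
#'             dimnames = list(c("iso1", "iso2"), c("e1", "e2")))
#' em <- expression_matrix(m, space = "fpkm")
#' log_transform(em)
#' @export
expression_matrix <- function(values, space = c("fpkm", "log2"), sentinel = -15) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs isoform row names and experiment column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate isoform ids in expression matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate experiment ids in expression matrix")
  if (space == "fpkm") {
    if (any(values < 0, na.rm = TRUE))
      stop("negative FPKM values are not allowed")
  } else {
    if (!all(is.finite(values)))
      stop("log2-space matrix must be all finite (missing cells = sentinel)")
  }
  structure(list(values = values, space = space, sentinel = sentinel),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d isoforms x %d experiments [%s space]\n",
              nrow(x$values), ncol(x$values), x$space))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expression_matrix`.
#' @export
isoform_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
experiment_ids <- function(x) colnames(x$values)

#' Subset an expression matrix by isoform and/or experiment
#'
#' @param x an `expression_matrix`.
#' @param isoforms,experiments character vectors of ids to keep (default all).
#' @return An `expression_matrix` restricted to the requested rows/columns.
#' @export
subset_matrix <- function(x, isoforms = NULL, experiments = NULL) {
  v <- x$values
  if (!is.null(isoforms)) {
    missing <- setdiff(isoforms, rownames(v))
    if (length(missing))
      stop("unknown isoform id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[isoforms, , drop = FALSE]
  }
  if (!is.null(experiments)) {
    missing <- setdiff(experiments, colnames(v))
    if (length(missing))
      stop("unknown experiment id(s): ", paste(utils::head(missing, 5), collapse = ", "))
    v <- v[, experiments, drop = FALSE]
  }
  expression_matrix(v, space = x$space, sentinel = x$sentinel)
}
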
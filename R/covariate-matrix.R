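#' Covariate matrix of candidate sampling units
#'
#' Bundles an `n x d` numeric matrix of unit-level covariates with unique
#' unit identifiers.  This is the basic input of every allocation routine in
#' the package: rows are candidate sampling units (e.g. census sectors),
#' columns are the covariates whose between-group balance is to be
#' controlled.
#'
#' @param values Numeric matrix (or data frame of numeric columns) with `n`
#'   rows and `d` columns.  All entries must be finite; missing values are an
#'   error (no imputation is performed).
#' @param unit_ids Character vector of `n` unique unit identifiers.  Defaults
#'   to the row names of `values`, or `"unit_1" ... "unit_n"` when absent.
#'
#' @return An object of class `"covariate_matrix"`: a list with elements
#'   `unit_ids`, `values` (numeric matrix with column names), `n` and `d`.
#'
#' @examples
#' x <- covariate_matrix(cbind(income = c(10, 20, 30, 40),
#'                             age    = c(30, 40, 50, 60)))
#' x$n
#' @export
covariate_matrix <- function(values, unit_ids = NULL) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix or all-numeric data frame")
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2L) stop("need at least 2 units (rows)")
  if (d < 1L) stop("need at least 1 covariate (column)")
  if (anyNA(values) || !all(is.finite(values)))
    stop("covariate values must all be finite; missing values are not supported")
  if (is.null(unit_ids)) {
    unit_ids <- rownames(values)
    if (is.null(unit_ids)) unit_ids <- paste0("unit_", seq_len(n))
  }
  unit_ids <- as.character(unit_ids)
  if (length(unit_ids) != n) stop("'unit_ids' must have one entry per row")
  if (anyDuplicated(unit_ids)) stop("'unit_ids' must be unique")
  if (is.null(colnames(values))) colnames(values) <- paste0("x", seq_len(d))
  rownames(values) <- NULL
  structure(list(unit_ids = unit_ids, values = values, n = n, d = d),
            class = "covariate_matrix")
}

#' Coerce to a covariate matrix
#'
#' @param x A `"covariate_matrix"`, numeric matrix, or data frame.  A data
#'   frame whose first column is character/factor is interpreted as an
#'   identifier column followed by numeric covariates.
#' @return A `"covariate_matrix"`.
#' @export
as_covariate_matrix <- function(x) {
  if (inherits(x, "covariate_matrix")) return(x)
  if (is.data.frame(x) && ncol(x) >= 2L &&
      (is.character(x[[1L]]) || is.factor(x[[1L]]))) {
    ids <- as.character(x[[1L]])
    vals <- as.matrix(x[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    return(covariate_matrix(vals, unit_ids = ids))
  }
  covariate_matrix(x)
}

#' Read a covariate table from CSV
#'
#' Expects a header row; the first column holds unit identifiers and the
#' remaining columns numeric covariates.  Missing values are an error.
#'
#' @param path Path to a CSV file.
#' @return A `"covariate_matrix"`.
#' @export
read_covariates <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an identifier column plus >= 1 covariate column")
  ids <- as.character(df[[1L]])
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("covariate columns must be numeric")
  storage.mode(vals) <- "double"
  covariate_matrix(vals, unit_ids = ids)
}

#' Write a covariate table to CSV
#'
#' @param x A `"covariate_matrix"`.
#' @param path Output path.
#' @param id_column Name of the identifier column (default `"unit_id"`).
#' @return `path`, invisibly.
#' @export
write_covariates <- function(x, path, id_column = "unit_id") {
  x <- as_covariate_matrix(x)
  df <- data.frame(x$unit_ids, x$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1L] <- id_column
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.covariate_matrix <- function(x, ...) {
  cat("Covariate matrix:", x$n, "units x", x$d, "covariates\n")
  cat("Covariates:", paste(colnames(x$values), collapse = ", "), "\n")
  cat("First units:", paste(head(x$unit_ids, 5L), collapse = ", "),
      if (x$n > 5L) "...\n" else "\n")
  invisible(x)
}

# internal: numeric values of a covariate-matrix-like input
cov_values <- function(x) as_covariate_matrix(x)$values
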
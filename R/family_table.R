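#' Construct a family BMI table
#'
#' A `family_table` holds one family per row and seven BMI columns in the
#' fixed role order `child, mother, father, mgm, mgf, pgm, pgf`. Missing
#' entries are `NA` in `values` and `FALSE` in the aligned logical `mask`
#' (`TRUE` = observed). When the table was produced by masking a complete
#' simulated table, the complete matrix is retained in `truth` for scoring
#' oracles only; no imputation routine ever reads it.
#'
#' @param values numeric n x 7 matrix (NA where unobserved).
#' @param mask logical n x 7 matrix, `TRUE` = observed. Defaults to
#'   `!is.na(values)`.
#' @param truth optional complete n x 7 matrix of the pre-masking values.
#' @param imputed optional logical n x 7 matrix marking cells that were filled
#'   in by an imputation routine (complete tables only).
#' @return an object of class `family_table`.
#' @export
family_table <- function(values, mask = NULL, truth = NULL, imputed = NULL) {
  values <- as.matrix(values)
  if (ncol(values) != 7L) {
    stop("a family table must have exactly 7 columns (", paste(FAMILY_ROLES, collapse = ", "), ")")
  }
  colnames(values) <- FAMILY_ROLES
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  colnames(mask) <- FAMILY_ROLES
  stopifnot(all(dim(mask) == dim(values)))
  if (any(mask & !is.finite(values))) {
    stop("observed cells (mask TRUE) must hold finite BMI values")
  }
  values[!mask] <- NA_real_
  if (!is.null(truth)) {
    truth <- as.matrix(truth)
    colnames(truth) <- FAMILY_ROLES
    stopifnot(all(dim(truth) == dim(values)))
  }
  structure(
    list(values = values, mask = mask, roles = FAMILY_ROLES,
         truth = truth, imputed = imputed),
    class = "family_table"
  )
}

#' @export
print.family_table <- function(x, ...) {
  n <- nrow(x$values)
  miss <- if (n > 0) round(colMeans(!x$mask), 3) else rep(NA_real_, 7)
  cat("family_table:", n, "families x 7 roles\n")
  cat("missing fraction per role:\n")
  print(miss)
  invisible(x)
}

#' @export
dim.family_table <- function(x) dim(x$values)

#' Number of families in a table
#' @param table a `family_table`.
#' @return integer row count.
#' @export
n_families <- function(table) nrow(table$values)

#' Is every cell of the table observed?
#' @param table a `family_table`.
#' @return logical scalar.
#' @export
is_complete <- function(table) all(table$mask)

#' Summarise the missingness of a family table
#'
#' @param table a `family_table`.
#' @return a list with `fractions` (named per-role missing fractions, column
#'   means of the negated mask) and `n_patterns` (number of distinct row-wise
#'   missingness patterns).
#' @export
missingness_summary <- function(table) {
  stopifnot(inherits(table, "family_table"))
  n <- n_families(table)
  if (n == 0L) {
    return(list(fractions = stats::setNames(rep(0, 7), FAMILY_ROLES), n_patterns = 0L))
  }
  fractions <- colMeans(!table$mask)
  keys <- apply(table$mask, 1L, function(r) paste(as.integer(r), collapse = ""))
  list(fractions = fractions, n_patterns = length(unique(keys)))
}

#' Write a family table to CSV
#'
#' One family per row, header `child,mother,father,mgm,mgf,pgm,pgf`, missing
#' entries written as empty fields. The oracle `truth` sheet is never written.
#'
#' @param table a `family_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_family_csv <- function(table, path) {
  stopifnot(inherits(table, "family_table"))
  df <- as.data.frame(table$values)
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read a family table from CSV
#'
#' @param path CSV file written by [write_family_csv()] (or any CSV with the
#'   seven role columns; empty fields become missing cells).
#' @return a `family_table`.
#' @export
read_family_csv <- function(path) {
  df <- utils::read.csv(path, header = TRUE)
  if (!all(FAMILY_ROLES %in% names(df))) {
    stop("CSV must contain columns: ", paste(FAMILY_ROLES, collapse = ", "))
  }
  family_table(as.matrix(df[, FAMILY_ROLES, drop = FALSE]))
}
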
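#' Construct a labelled distance matrix
#'
#' Validates symmetry (within 1e-9), zero diagonal, non-negativity and
#' unique labels, returning a plain numeric matrix of class `dist_matrix`.
#'
#' @param values square numeric matrix with matching row/col names.
#' @return a `dist_matrix`.
#' @export
dist_matrix <- function(values) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("distance matrix must be square")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("distance matrix must be labelled")
  }
  if (!identical(rownames(values), colnames(values))) {
    stop("row and column labels differ")
  }
  if (anyDuplicated(rownames(values))) stop("duplicated labels")
  if (anyNA(values)) stop("missing values in distance matrix")
  if (max(abs(values - t(values))) > 1e-9) stop("matrix is asymmetric beyond 1e-9")
  if (any(abs(diag(values)) > 1e-9)) stop("nonzero diagonal")
  if (any(values < -1e-12)) stop("negative distances")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  values[values < 0] <- 0
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  ut <- x[upper.tri(x)]
  cat(sprintf("dist_matrix: %d labels, mean %.4f, range [%.4f, %.4f]\n",
              nrow(x), mean(ut), min(ut), max(ut)))
  invisible(x)
}

#' Write a distance matrix to square TSV
#'
#' Values are written with 12 significant digits so a write/read round trip
#' is lossless to that precision.
#'
#' @param dm a [dist_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  m <- format(unclass(dm), digits = 12, scientific = TRUE, trim = TRUE)
  df <- data.frame(id = rownames(dm), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distance matrix from square TSV
#' @param path input path written by [write_distance_matrix()] or compatible.
#' @return a [dist_matrix()].
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE, comment.char = "")
  m <- as.matrix(df)
  if (!identical(rownames(m), colnames(m))) {
    stop("label mismatch between header and rows in ", path)
  }
  dist_matrix(m)
}

#' Align a distance matrix to a label set
#' @param dm a [dist_matrix()].
#' @param labels character vector, subset of the matrix labels.
#' @return the reordered submatrix as a [dist_matrix()].
#' @export
align_dm <- function(dm, labels) {
  missing <- setdiff(labels, rownames(dm))
  if (length(missing)) {
    stop("labels absent from distance matrix: ", paste(missing, collapse = ", "))
  }
  dist_matrix(unclass(dm)[labels, labels, drop = FALSE])
}
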
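#' Expression matrix with a declared value space
#'
#' A lightweight feature-by-sample container: a numeric matrix with row
#' (feature) and column (sample) identifiers plus a declared value space.
#' Every analysis stage checks the space it requires rather than guessing
#' from the values.
#'
#' @param values numeric matrix, features in rows, samples in columns; must
#'   carry row and column names.
#' @param space one of `"counts"`, `"log2norm"`, `"Ct"`, `"beta"`, `"M"`.
#' @return An object of class `expr_matrix`: the matrix with a `space`
#'   attribute.
#' @details Invariants enforced at construction: no duplicated feature or
#'   sample identifiers; `beta` values strictly inside (0, 1); `counts`
#'   non-negative. Violations raise an error naming the offending
#'   identifier.
#' @export
expression_matrix <- function(values, space = c("counts", "log2norm", "Ct", "beta", "M")) {
  space <- match.arg(space)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have feature (row) and sample (column) identifiers")
  dup_f <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_f))
    stop("duplicated feature identifier(s): ", paste(unique(dup_f), collapse = ", "))
  dup_s <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_s))
    stop("duplicated sample identifier(s): ", paste(unique(dup_s), collapse = ", "))
  if (any(!is.finite(values)))
    stop("non-finite values are not allowed")
  if (space == "beta" && (any(values <= 0) || any(values >= 1)))
    stop("beta-space values must lie strictly inside (0, 1)")
  if (space == "counts" && any(values < 0))
    stop("counts must be non-negative")
  structure(values, space = space, class = c("expr_matrix", "matrix", "array"))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d features x %d samples, space = %s\n",
              nrow(x), ncol(x), attr(x, "space")))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x object to query.
#' @export
matrix_space <- function(x) {
  sp <- attr(x, "space")
  if (is.null(sp)) stop("object has no declared value space")
  sp
}

assert_space <- function(x, space) {
  if (!identical(matrix_space(x), space))
    stop(sprintf("matrix must be in '%s' space, got '%s'", space, matrix_space(x)))
  invisible(x)
}

# Rebuild an expr_matrix after a transform, keeping dimnames.
new_space <- function(values, template, space) {
  dimnames(values) <- dimnames(template)[seq_along(dim(values))]
  expression_matrix(values, space)
}

#' Read / write feature-by-sample TSV matrices
#'
#' Tab-delimited text with a header row of sample identifiers; the first
#' column holds feature identifiers. `write_matrix()` then `read_matrix()`
#' round-trips values exactly (up to numeric formatting at 15 significant
#' digits).
#'
#' @param path file path.
#' @param space declared value space of the stored matrix.
#' @return `read_matrix()` returns an [expression_matrix()].
#' @export
read_matrix <- function(path, space = c("counts", "log2norm", "Ct", "beta", "M")) {
  space <- match.arg(space)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L) stop("expected a feature-id column plus >= 1 sample column in ", path)
  ids <- raw[[1L]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicated feature identifier(s) in ", path, ": ", paste(dup, collapse = ", "))
  num <- suppressWarnings(vapply(raw[-1L], as.numeric, numeric(nrow(raw))))
  if (nrow(raw) == 1L) num <- matrix(num, nrow = 1L, dimnames = list(NULL, names(raw)[-1L]))
  bad <- which(apply(is.na(num), 1L, any))
  if (length(bad))
    stop("non-numeric cell(s) in ", path, " at data row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  rownames(num) <- ids
  expression_matrix(num, space)
}

#' @rdname read_matrix
#' @param matrix an [expression_matrix()] (or plain named matrix).
#' @export
write_matrix <- function(matrix, path) {
  df <- data.frame(feature_id = rownames(matrix),
                   format(unclass(matrix), digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE)
  colnames(df) <- c("feature_id", colnames(matrix))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
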
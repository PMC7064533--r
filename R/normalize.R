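#' Median-of-ratios size-factor normalization
#'
#' Classical median-of-ratios normalization for count matrices: each
#' sample's size factor is the median, over reference features, of the
#' ratio of its count to the feature's geometric mean across samples.
#' Reference features are those with strictly positive counts in every
#' sample. Output values are `log2(count / size_factor + 1)`.
#'
#' @param counts an [expression_matrix()] in `counts` space.
#' @return An `expr_matrix` in `log2norm` space, with the per-sample size
#'   factors attached as attribute `size_factors`.
#' @export
size_factor_normalize <- function(counts) {
  assert_space(counts, "counts")
  x <- unclass(counts)
  ref <- rowSums(x > 0) == ncol(x)
  if (!any(ref))
    stop("no reference features: every feature has a zero count in some sample; ",
         "pseudo-reference fallback is disabled")
  log_geo <- rowMeans(log(x[ref, , drop = FALSE]))
  sf <- apply(log(x[ref, , drop = FALSE]), 2L, function(col) exp(stats::median(col - log_geo)))
  out <- log2(sweep(x, 2L, sf, "/") + 1)
  out <- new_space(out, counts, "log2norm")
  attr(out, "size_factors") <- sf
  out
}

#' 2^-deltaCt transformation of qRT-PCR Ct values
#'
#' Converts cycle-threshold values to relative expression against an
#' endogenous control: `2^-(Ct_target - Ct_reference)` per sample. The
#' reference feature is removed from the output.
#'
#' @param ct an [expression_matrix()] in `Ct` space.
#' @param reference_feature identifier of the endogenous control feature.
#' @return An `expr_matrix` in `log2norm` space holding the relative
#'   expression values (linear scale 2^-dCt; log-transform downstream if
#'   required).
#' @export
delta_ct_transform <- function(ct, reference_feature) {
  assert_space(ct, "Ct")
  if (!reference_feature %in% rownames(ct))
    stop("reference feature '", reference_feature, "' absent from the Ct matrix")
  ref <- unclass(ct)[reference_feature, ]
  if (any(!is.finite(ref)))
    stop("reference feature '", reference_feature, "' missing in >= 1 sample")
  x <- unclass(ct)[setdiff(rownames(ct), reference_feature), , drop = FALSE]
  out <- 2^(-sweep(x, 2L, ref, "-"))
  expression_matrix(out, "log2norm")
}

#' Convert methylation beta values to M values
#'
#' `M = log2(beta / (1 - beta))`, with beta clamped to
#' `[epsilon, 1 - epsilon]` to keep M finite at the extremes.
#'
#' @param beta an [expression_matrix()] in `beta` space.
#' @param epsilon positive clamp margin.
#' @return An `expr_matrix` in `M` space.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  assert_space(beta, "beta")
  if (!is.numeric(epsilon) || epsilon <= 0) stop("`epsilon` must be > 0")
  b <- pmin(pmax(unclass(beta), epsilon), 1 - epsilon)
  new_space(log2(b / (1 - b)), beta, "M")
}

#' Drop the least-variant features
#'
#' Retains the `ceiling((1 - drop_fraction) * F)` features with the largest
#' sample variance; ties in variance are broken by feature-id lexicographic
#' order (the lexicographically smaller id is kept first).
#'
#' @param matrix an [expression_matrix()].
#' @param drop_fraction fraction of features to drop, in `[0, 1)`.
#' @return The filtered matrix, original feature order preserved.
#' @export
variance_filter <- function(matrix, drop_fraction) {
  if (!is.numeric(drop_fraction) || drop_fraction < 0 || drop_fraction >= 1)
    stop("`drop_fraction` must lie in [0, 1)")
  if (drop_fraction == 0) return(matrix)
  v <- apply(unclass(matrix), 1L, stats::var)
  keep_n <- as.integer(ceiling((1 - drop_fraction) * nrow(matrix)))
  ord <- order(-v, rownames(matrix))
  keep <- sort(ord[seq_len(keep_n)])
  out <- unclass(matrix)[keep, , drop = FALSE]
  expression_matrix(out, matrix_space(matrix))
}

#' Drop features below a minimum annotated length
#'
#' Removes features whose annotated transcript length is strictly less
#' than `min_length` (a feature exactly at the threshold is retained).
#'
#' @param matrix an [expression_matrix()].
#' @param annotation named numeric vector, feature id -> length in bases.
#' @param min_length minimum length retained (default 200).
#' @return The filtered matrix; warns if nothing survives.
#' @export
length_filter <- function(matrix, annotation, min_length = 200) {
  missing <- setdiff(rownames(matrix), names(annotation))
  if (length(missing))
    stop("unannotated feature(s): ", paste(missing, collapse = ", "))
  len <- annotation[rownames(matrix)]
  keep <- len >= min_length
  if (!any(keep)) warning("length filter removed every feature")
  out <- unclass(matrix)[keep, , drop = FALSE]
  if (!is.matrix(out)) out <- matrix(out, nrow = 0L, ncol = ncol(matrix),
                                     dimnames = list(NULL, colnames(matrix)))
  structure(out, space = matrix_space(matrix), class = c("expr_matrix", "matrix", "array"))
}
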
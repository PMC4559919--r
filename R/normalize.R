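#' Build a quantile-normalization reference distribution
#'
#' The reference is the mean, across columns, of each column's order
#' statistics: `sorted_values[i] = mean_j(sort(column_j)[i])`.
#'
#' @param m Numeric matrix with at least one column.
#' @return Non-decreasing numeric vector of length `nrow(m)`.
#' @export
quantile_reference <- function(m) {
  if (is.null(dim(m)) || ncol(m) < 1L) stopf("need a matrix with >= 1 column")
  rowMeans(apply(m, 2L, sort))
}

#' Quantile-normalize the columns of a matrix
#'
#' Each column's values are replaced by the reference values at their
#' within-column ranks; tied values receive the mean of the reference
#' values at the tied rank positions (average-ties rule).  Two modes:
#'
#' * joint (`reference = NULL`): the reference is built from the input
#'   itself, so after normalization every column's sorted vector equals the
#'   reference exactly.  Pooling training and test columns and normalizing
#'   them together reproduces the joint protocol used when applying a
#'   trained model to archived samples.
#' * frozen (`reference` given, e.g. built on training columns only): test
#'   columns are projected onto the stored distribution without touching
#'   training data, the mode suited to prospective use.
#'
#' Responses (RPKM) and predictors (intensities) should be normalized with
#' separate references, never pooled across data kinds.
#'
#' @param m Numeric matrix.
#' @param reference Optional sorted reference vector of length `nrow(m)`
#'   (see [quantile_reference()]).
#' @return Matrix of the same shape and dimnames.
#' @export
quantile_normalize <- function(m, reference = NULL) {
  if (is.null(reference)) reference <- quantile_reference(m)
  if (length(reference) != nrow(m))
    stopf("reference length %d does not match row count %d",
          length(reference), nrow(m))
  ref <- sort(reference)
  out <- apply(m, 2L, function(x) {
    v <- numeric(length(x))
    v[order(x)] <- ref
    # average the reference values across tied positions
    stats::ave(v, match(x, x), FUN = mean)
  })
  dimnames(out) <- dimnames(m)
  if (identical(attr(m, "scale_tag"), "rpkm"))
    attr(out, "scale_tag") <- "normalized_rpkm"
  else attr(out, "scale_tag") <- attr(m, "scale_tag")
  out
}
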
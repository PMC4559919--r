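#' Median polish decomposition
#'
#' Tukey's median polish: alternating subtraction of row and column
#' medians decomposes a matrix into `overall + row + col + residuals`
#' (the reconstruction is exact at every iteration).  Sweeps stop when the
#' absolute change in the sum of absolute residuals falls below `tol`, or
#' after `max_iter` full sweeps.  This is the probe-set summarization step
#' of RMA when applied to log2 probe intensities.
#'
#' @param x Numeric matrix (probes x samples), all values finite.
#' @param max_iter Maximum number of full row+column sweeps.
#' @param tol Convergence tolerance on the change in `sum(abs(residuals))`.
#' @return List with `overall`, `row` (row effects), `col` (column
#'   effects), `residuals`, `iterations`.
#' @export
median_polish <- function(x, max_iter = 10, tol = 0.01) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stopf("median polish requires finite values")
  if (!nrow(x) || !ncol(x)) stopf("need a non-empty matrix")
  overall <- 0
  re <- numeric(nrow(x))
  ce <- numeric(ncol(x))
  res <- x
  oldsum <- sum(abs(res))
  it <- 0L
  for (i in seq_len(max_iter)) {
    it <- i
    rd <- apply(res, 1L, stats::median)
    re <- re + rd
    res <- res - rd
    d <- stats::median(ce)
    ce <- ce - d
    overall <- overall + d
    cd <- apply(res, 2L, stats::median)
    ce <- ce + cd
    res <- res - rep(cd, each = nrow(res))
    d <- stats::median(re)
    re <- re - d
    overall <- overall + d
    newsum <- sum(abs(res))
    if (abs(newsum - oldsum) < tol) break
    oldsum <- newsum
  }
  list(overall = overall, row = stats::setNames(re, rownames(x)),
       col = stats::setNames(ce, colnames(x)), residuals = res,
       iterations = it)
}

#' Median-polish probe-set summarization (RMA-style baseline)
#'
#' The conventional summarization baseline: for each feature, its probe
#' rows are log2-transformed (with a +1 offset guarding zero intensities)
#' and median-polished; `overall + column effect` is reported as the
#' per-sample expression.  Output is on an arbitrary log2 scale — unlike
#' the forest models it carries no absolute-scale information.
#'
#' @param intensities Probe intensity matrix, probes x samples, linear scale.
#' @param map Feature-to-probe map (named list).
#' @param max_iter,tol Passed to [median_polish()].
#' @param offset Added before the log2 transform.
#' @return Features x samples expression matrix
#'   (`scale_tag = "arbitrary"`); features with no present probes are
#'   skipped and listed in the `"skipped"` attribute.
#' @export
summarize_probes <- function(intensities, map, max_iter = 10, tol = 0.01,
                             offset = 1) {
  feats <- names(map)
  present <- lapply(map, function(p) p[p %in% rownames(intensities)])
  keep <- lengths(present) > 0L
  out <- matrix(NA_real_, sum(keep), ncol(intensities),
                dimnames = list(feats[keep], colnames(intensities)))
  for (f in feats[keep]) {
    sub <- log2(intensities[present[[f]], , drop = FALSE] + offset)
    mp <- median_polish(sub, max_iter = max_iter, tol = tol)
    out[f, ] <- mp$overall + mp$col
  }
  attr(out, "scale_tag") <- "arbitrary"
  attr(out, "skipped") <- feats[!keep]
  out
}
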
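# Agreement statistics between an estimated and a reference expression
# matrix, and rank-concordance statistics for differential-expression
# orderings.

align_matrices <- function(est, truth) {
  feats <- intersect(rownames(est), rownames(truth))
  samples <- intersect(colnames(est), colnames(truth))
  if (length(feats) < 1L || length(samples) < 1L)
    stopf("matrices share no feature/sample ids")
  list(est = est[feats, samples, drop = FALSE],
       truth = truth[feats, samples, drop = FALSE],
       features = feats, samples = samples)
}

safe_cor <- function(x, y, method = "pearson") {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(x[ok], y[ok], method = method)
}

#' Within-sample and cross-sample agreement with a reference
#'
#' Within-sample correlations (per shared sample, across shared features)
#' measure agreement on the relative expression of genes inside one
#' sample; cross-sample correlations (per shared feature, across shared
#' samples) measure how well variation across samples is captured.  Both
#' Pearson and Spearman (average ranks for ties) are reported.  Undefined
#' correlations (constant vectors) are flagged `NA` and excluded from the
#' means, with counts reported.
#'
#' @param est,truth Expression matrices sharing >= 3 feature and >= 3
#'   sample ids.
#' @param feature_subset Optional feature ids to restrict to.
#' @return List of class `correlation_report`: `per_sample` and
#'   `per_feature` data frames, and a `summary` with mean/median Pearson
#'   (`r_bar`) and Spearman (`rho_bar`) and the defined-value counts.
#' @export
correlation_report <- function(est, truth, feature_subset = NULL) {
  if (!is.null(feature_subset)) {
    est <- est[rownames(est) %in% feature_subset, , drop = FALSE]
    truth <- truth[rownames(truth) %in% feature_subset, , drop = FALSE]
  }
  al <- align_matrices(est, truth)
  if (length(al$features) < 3L || length(al$samples) < 3L)
    stopf("need >= 3 shared features and samples")
  per_sample <- data.frame(
    sample_id = al$samples,
    pearson = vapply(al$samples, function(s)
      safe_cor(al$est[, s], al$truth[, s]), 0, USE.NAMES = FALSE),
    spearman = vapply(al$samples, function(s)
      safe_cor(al$est[, s], al$truth[, s], "spearman"), 0,
      USE.NAMES = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  per_feature <- data.frame(
    feature_id = al$features,
    pearson = vapply(al$features, function(f)
      safe_cor(al$est[f, ], al$truth[f, ]), 0, USE.NAMES = FALSE),
    spearman = vapply(al$features, function(f)
      safe_cor(al$est[f, ], al$truth[f, ], "spearman"), 0,
      USE.NAMES = FALSE),
    row.names = NULL, stringsAsFactors = FALSE)
  msum <- function(x) c(mean = mean(x, na.rm = TRUE),
                        median = stats::median(x, na.rm = TRUE),
                        n_defined = sum(!is.na(x)))
  structure(list(per_sample = per_sample, per_feature = per_feature,
                 summary = list(
                   within_pearson = msum(per_sample$pearson),
                   within_spearman = msum(per_sample$spearman),
                   cross_pearson = msum(per_feature$pearson),
                   cross_spearman = msum(per_feature$spearman),
                   r_bar = mean(per_feature$pearson, na.rm = TRUE),
                   rho_bar = mean(per_feature$spearman, na.rm = TRUE))),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("within-sample:  r = %.3f (median %.3f, n = %d)\n",
              s$within_pearson[1], s$within_pearson[2], s$within_pearson[3]))
  cat(sprintf("cross-sample:   r_bar = %.3f, rho_bar = %.3f (n = %d)\n",
              s$r_bar, s$rho_bar, s$cross_pearson[3]))
  invisible(x)
}

#' Relative-error summary against a reference
#'
#' Per-observation relative error `(est - truth) / truth`, restricted to
#' observations with reference values inside `[truth_min, truth_max]`
#' (excluding the high-stochasticity low end and zero references, whose
#' count is reported).  Median error and median absolute error summarize
#' all windowed observations; for display, observations with relative
#' error at or above `relerr_cap` are excluded and the remainder, ordered
#' by reference value, is averaged in bins of `bin_size` consecutive
#' observations.
#'
#' @param est,truth Aligned expression matrices (or vectors).
#' @param truth_min,truth_max Reference window, default \[1, 1000\].
#' @param relerr_cap Display cap on relative error, default 2.
#' @param bin_size Observations per display bin, default 75.
#' @return List with `median_error`, `median_abs_error`, `n_used`,
#'   `n_zero_excluded`, `n_capped` and a `bins` data frame
#'   (`mean_truth`, `mean_relerr`).
#' @export
relative_error_summary <- function(est, truth, truth_min = 1,
                                   truth_max = 1000, relerr_cap = 2,
                                   bin_size = 75) {
  if (is.matrix(est)) {
    al <- align_matrices(est, truth)
    e <- as.vector(al$est); tr <- as.vector(al$truth)
  } else { e <- est; tr <- truth }
  win <- tr >= truth_min & tr <= truth_max
  zero <- win & tr == 0
  use <- win & !zero
  rel <- (e[use] - tr[use]) / tr[use]
  tu <- tr[use]
  capped <- rel >= relerr_cap
  disp <- order(tu[!capped])
  rel_d <- rel[!capped][disp]
  tr_d <- tu[!capped][disp]
  nb <- length(rel_d) %/% bin_size
  bins <- if (nb >= 1L) {
    idx <- rep(seq_len(nb), each = bin_size)
    used <- seq_len(nb * bin_size)
    data.frame(mean_truth = tapply(tr_d[used], idx, mean),
               mean_relerr = tapply(rel_d[used], idx, mean),
               row.names = NULL)
  } else data.frame(mean_truth = numeric(0), mean_relerr = numeric(0))
  list(median_error = stats::median(rel),
       median_abs_error = stats::median(abs(rel)),
       n_used = sum(use), n_zero_excluded = sum(zero),
       n_capped = sum(capped), bins = bins)
}

#' Per-sample regression slope of estimates on the reference
#'
#' Ordinary least-squares slope of `est` on `truth` within each sample; a
#' method that recovers expression on the reference's absolute scale has
#' slopes close to unity, while summarization output on an unrelated scale
#' does not.
#'
#' @param est,truth Aligned expression matrices (>= 3 shared features).
#' @return List with per-sample `slopes` (named, `NA` where the reference
#'   is constant) and `median_slope`.
#' @export
within_sample_slope <- function(est, truth) {
  al <- align_matrices(est, truth)
  if (length(al$features) < 3L) stopf("need >= 3 shared features")
  slopes <- vapply(al$samples, function(s) {
    x <- al$truth[, s]; y <- al$est[, s]
    vx <- stats::var(x)
    if (!is.finite(vx) || vx == 0) return(NA_real_)
    stats::cov(x, y) / vx
  }, 0)
  list(slopes = slopes, median_slope = stats::median(slopes, na.rm = TRUE))
}

#' Rank features by differential expression between two groups
#'
#' Per-feature two-sided Welch t-tests between the two sample groups,
#' Benjamini-Hochberg adjustment as the q-value, and a deterministic rank
#' by ascending q, breaking ties by ascending p and then feature id.
#' Features with zero variance in both groups and equal means get p = 1.
#'
#' @param m Expression matrix, features x samples.
#' @param groupA,groupB Disjoint sample id vectors, each of size >= 2.
#' @return `data.frame` with `feature_id`, `t`, `p`, `q`, `rank` (a
#'   permutation of `1..nrow(m)`), ordered as the input features.
#' @export
de_rank <- function(m, groupA, groupB) {
  if (length(intersect(groupA, groupB))) stopf("groups must be disjoint")
  if (length(groupA) < 2L || length(groupB) < 2L)
    stopf("each group needs >= 2 samples")
  A <- m[, groupA, drop = FALSE]
  B <- m[, groupB, drop = FALSE]
  nA <- ncol(A); nB <- ncol(B)
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- apply(A, 1L, stats::var); vB <- apply(B, 1L, stats::var)
  se2 <- vA / nA + vB / nB
  tstat <- (mA - mB) / sqrt(se2)
  df <- se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  degen <- se2 == 0
  tstat[degen & mA == mB] <- 0
  p[degen & mA == mB] <- 1
  tstat[degen & mA != mB] <- sign(mA - mB)[degen & mA != mB] * Inf
  p[degen & mA != mB] <- 0
  q <- stats::p.adjust(p, method = "BH")
  ord <- order(q, p, rownames(m))
  rk <- integer(nrow(m))
  rk[ord] <- seq_len(nrow(m))
  data.frame(feature_id = rownames(m), t = unname(tstat), p = unname(p),
             q = unname(q), rank = rk, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Lin's concordance correlation coefficient
#'
#' Measures both correlation and closeness to the identity line:
#' `rho_c = 2 cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)`,
#' with population (1/n) moments.  Used here to compare two
#' differential-expression rank vectors.  `|rho_c| <= |r|` always, with
#' equality iff the means and variances agree.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A value in \[-1, 1\], or `NA` when both vectors are constant.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y)) stopf("vectors must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need length >= 3")
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  den <- vx + vy + (mx - my)^2
  if (den == 0) return(NA_real_)
  2 * cxy / den
}

#' Cumulative Jaccard index of two rankings
#'
#' For two orderings of the same feature universe,
#' `J(k) = |topA(k) intersect topB(k)| / |topA(k) union topB(k)|` traced
#' over `k = 1..N`; `J(N)` is always 1.  Tracks how quickly two
#' differential-expression rankings agree on their top lists.
#'
#' @param rankA,rankB Character vectors giving the features in rank order
#'   (permutations of one another).
#' @return Numeric vector `J(1..N)`.
#' @export
cumulative_jaccard <- function(rankA, rankB) {
  if (!setequal(rankA, rankB) || length(rankA) != length(rankB) ||
      anyDuplicated(rankA) || anyDuplicated(rankB))
    stopf("rankings must be permutations of the same feature universe")
  n <- length(rankA)
  posB <- match(rankA, rankB)
  inA <- logical(n)  # indexed by position in rankB
  inB <- logical(n)
  inter <- 0L
  J <- numeric(n)
  for (k in seq_len(n)) {
    pa <- posB[k]        # rankA[k] at this position of rankB
    if (inB[pa]) inter <- inter + 1L
    inA[pa] <- TRUE
    if (inA[k]) inter <- inter + 1L   # rankB[k] already drawn by A
    inB[k] <- TRUE
    J[k] <- inter / (2 * k - inter)
  }
  J
}
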
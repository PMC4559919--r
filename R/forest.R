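#' Fit a quantile regression forest
#'
#' Grows `ntree` regression trees, each on a bootstrap sample (drawn with
#' replacement, size equal to the number of training samples), splitting by
#' variance reduction over `mtry` randomly chosen predictors per node and
#' stopping when children would fall below `min_node_size` samples.  Leaves
#' retain the distinct in-bag training-sample indices, which is what turns
#' the forest into a conditional-distribution estimator: any query point
#' induces a weight over training samples (see [qrf_weights()]) from which
#' conditional means and quantiles are read off.
#'
#' With a matrix response, splits maximize the summed variance reduction
#' across responses, each response standardized to unit variance on the
#' training set before scoring; a single-column response reproduces the
#' univariate forest exactly under the same seed.
#'
#' Randomness comes from a private MINSTD stream seeded by `seed`; fits are
#' bit-reproducible and independent of R's RNG state.
#'
#' @param X Numeric predictor matrix, samples x predictors, with dimnames.
#' @param y Numeric response vector, or samples x responses matrix for
#'   multi-response trees.
#' @param ntree Number of trees.
#' @param mtry Predictors sampled per split; default `max(1, floor(p/3))`.
#' @param min_node_size Minimum samples per terminal node.
#' @param seed Positive integer seed for the forest's private RNG.
#' @return An object of class `qr_forest`.
#' @examples
#' X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("p", 1:4)))
#' y <- X[, 1] + rnorm(50, sd = 0.1)
#' f <- qr_forest(X, y, ntree = 50, seed = 7)
#' predict(f, X[1:3, ])
#' predict(f, X[1:3, ], quantiles = c(0.05, 0.95))
#' @export
qr_forest <- function(X, y, ntree = 500, mtry = NULL, min_node_size = 5,
                      seed = 1) {
  X <- as.matrix(X)
  Y <- if (is.matrix(y)) y else matrix(y, ncol = 1L)
  if (nrow(X) != nrow(Y)) stopf("X and y disagree on sample count")
  if (nrow(X) < 5L) stopf("need at least 5 training samples")
  if (ntree < 1L || min_node_size < 1L) stopf("ntree and min_node_size must be >= 1")
  p <- ncol(X)
  if (is.null(mtry) || identical(mtry, "default")) mtry <- max(1L, floor(p / 3))
  mtry <- min(as.integer(mtry), p)
  if (mtry < 1L) stopf("mtry must be >= 1")
  sds <- apply(Y, 2L, stats::sd)
  Ys <- Y
  for (j in seq_len(ncol(Y)))
    Ys[, j] <- if (sds[j] > 0) Y[, j] / sds[j] else 0
  grown <- qrf_grow_cpp(X, Ys, as.integer(ntree), mtry,
                        as.integer(min_node_size), as.numeric(seed))
  structure(list(trees = grown$trees, inbag = grown$inbag,
                 X = X, y = Y, n = nrow(X),
                 probe_ids = colnames(X), sample_ids = rownames(X),
                 response_names = colnames(Y),
                 ntree = as.integer(ntree), mtry = mtry,
                 min_node_size = as.integer(min_node_size),
                 seed = as.numeric(seed)),
            class = "qr_forest")
}

# align new data to the forest's predictor set; hard error naming any
# missing probe
align_newdata <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L,
                                               dimnames = list(NULL, names(newdata)))
  ids <- object$probe_ids
  if (!is.null(ids)) {
    if (is.null(colnames(newdata)))
      stopf("newdata must carry predictor (probe) names")
    miss <- setdiff(ids, colnames(newdata))
    if (length(miss)) stopf("probe '%s' missing from newdata", miss[1L])
    newdata <- newdata[, ids, drop = FALSE]
  } else if (ncol(newdata) != ncol(object$X)) {
    stopf("newdata has %d predictors, forest expects %d",
          ncol(newdata), ncol(object$X))
  }
  newdata
}

leaf_ids <- function(tree, Xnew) {
  qrf_which_leaf_cpp(tree$split_var, tree$split_val, tree$left, tree$right,
                     Xnew)
}

#' Forest-induced weights over training samples
#'
#' For each query row, training sample i receives weight
#' `mean over trees of 1(i in leaf(x)) / (distinct in-bag count of that leaf)`.
#' Weights are non-negative and sum to one; the conditional mean is the
#' weighted mean of the training responses and conditional quantiles come
#' from the weighted empirical distribution.
#'
#' @param object A [qr_forest()] fit.
#' @param newdata Query matrix (samples x predictors) or single row.
#' @return Matrix of weights, query rows x training samples.
#' @export
qrf_weights <- function(object, newdata) {
  Xn <- align_newdata(object, newdata)
  m <- nrow(Xn)
  W <- matrix(0, m, object$n, dimnames = list(rownames(Xn), object$sample_ids))
  for (tree in object$trees) {
    lv <- leaf_ids(tree, Xn)
    for (i in seq_len(m)) {
      ls <- tree$leaf_samples[[lv[i]]]
      W[i, ls] <- W[i, ls] + 1 / length(ls)
    }
  }
  W / object$ntree
}

# per-node means of the stored responses over each leaf's distinct support
node_means <- function(tree, Y) {
  nr <- ncol(Y)
  v <- vapply(tree$leaf_samples,
              function(s) if (length(s)) colMeans(Y[s, , drop = FALSE])
              else numeric(nr),
              numeric(nr))
  if (nr == 1L) matrix(v, ncol = 1L) else t(v)
}

#' Predict from a quantile regression forest
#'
#' The point estimate is the forest mean: the average over trees of the
#' mean training response in the leaf the query reaches.  With `quantiles`
#' given, conditional quantiles are additionally computed from the
#' forest-weighted empirical distribution of training responses: the
#' q-quantile is the smallest response value whose cumulative weight
#' reaches q.  Quantile predictions therefore never extrapolate beyond the
#' training response range.
#'
#' @param object A [qr_forest()] fit.
#' @param newdata Predictor matrix or single named row.
#' @param quantiles Optional vector of probabilities in (0, 1).
#' @param ... Unused.
#' @return Without `quantiles`: a numeric vector (or matrix for
#'   multi-response forests).  With `quantiles`: a list with elements
#'   `mean` and `quantiles` (array query x quantile \[x response\]).
#' @export
predict.qr_forest <- function(object, newdata, quantiles = NULL, ...) {
  Xn <- align_newdata(object, newdata)
  m <- nrow(Xn)
  nr <- ncol(object$y)
  if (is.null(quantiles)) {
    acc <- matrix(0, m, nr)
    for (tree in object$trees) {
      nm <- node_means(tree, object$y)
      acc <- acc + nm[leaf_ids(tree, Xn), , drop = FALSE]
    }
    acc <- acc / object$ntree
    rownames(acc) <- rownames(Xn)
    colnames(acc) <- object$response_names
    return(if (nr == 1L) drop(acc) else acc)
  }
  if (any(quantiles <= 0 | quantiles >= 1)) stopf("quantiles must lie in (0, 1)")
  if (is.unsorted(quantiles, strictly = TRUE)) stopf("quantiles must be strictly increasing")
  W <- qrf_weights(object, Xn)
  qa <- array(NA_real_, c(m, length(quantiles), nr),
              dimnames = list(rownames(Xn), paste0("q", quantiles),
                              object$response_names))
  mean_pred <- W %*% object$y
  for (r in seq_len(nr)) {
    ord <- order(object$y[, r])
    ys <- object$y[ord, r]
    for (i in seq_len(m)) {
      cw <- cumsum(W[i, ord])
      for (k in seq_along(quantiles))
        qa[i, k, r] <- ys[which(cw >= quantiles[k] - 1e-12)[1L]]
    }
  }
  list(mean = if (nr == 1L) drop(mean_pred) else mean_pred,
       quantiles = if (nr == 1L) qa[, , 1L, drop = TRUE] else qa)
}

#' Out-of-bag estimates for the training samples
#'
#' Each training sample is predicted using only the trees whose bootstrap
#' excluded it — the forest's built-in cross-validation.  Samples that were
#' in-bag for every tree get `NA` (rare once `ntree` is a few hundred).
#'
#' @param object A [qr_forest()] fit.
#' @return Numeric vector (or matrix for multi-response forests) of OOB
#'   estimates, `NA` where undefined.
#' @export
oob_predict <- function(object) {
  n <- object$n
  nr <- ncol(object$y)
  acc <- matrix(0, n, nr)
  cnt <- integer(n)
  for (t in seq_len(object$ntree)) {
    oob <- which(object$inbag[, t] == 0L)
    if (!length(oob)) next
    tree <- object$trees[[t]]
    nm <- node_means(tree, object$y)
    acc[oob, ] <- acc[oob, ] + nm[leaf_ids(tree, object$X[oob, , drop = FALSE]), ,
                                  drop = FALSE]
    cnt[oob] <- cnt[oob] + 1L
  }
  out <- acc / cnt
  out[cnt == 0L, ] <- NA_real_
  rownames(out) <- object$sample_ids
  colnames(out) <- object$response_names
  if (nr == 1L) drop(out) else out
}

#' Cross-sample correlation of OOB estimates with the training response
#'
#' The Pearson correlation between out-of-bag estimates and the observed
#' training response, computed over samples with a defined OOB estimate.
#' It anticipates how well a gene's model will track held-out data and is
#' the statistic used to filter trained models.  Undefined (returned as
#' `NA`) with fewer than 3 complete pairs or when either vector is
#' constant.
#'
#' @param oob OOB estimates (possibly containing `NA`).
#' @param y Training response of the same length.
#' @return A single correlation in \[-1, 1\], or `NA`.
#' @export
oob_correlation <- function(oob, y) {
  ok <- !is.na(oob) & !is.na(y)
  if (sum(ok) < 3L) return(NA_real_)
  if (stats::sd(oob[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
  stats::cor(oob[ok], y[ok])
}

#' Select the probes most correlated with the response
#'
#' Ranks probes by the absolute Pearson correlation of their intensities
#' with the training response and keeps the strongest `n`.  Forests handle
#' sign-free monotone relations, so correlation strength rather than sign
#' is scored.  Zero-variance probes score 0; ties keep input order.
#'
#' @param X Training intensities, samples x probes.
#' @param y Training response vector.
#' @param n Number of probes to keep, or `"all"`.
#' @return Integer vector of selected probe column indices, strongest
#'   first (input order when `n = "all"`).
#' @export
select_probes <- function(X, y, n = "all") {
  p <- ncol(X)
  if (identical(n, "all")) return(seq_len(p))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stopf("n must be >= 1 or \"all\"")
  if (nrow(X) < 3L) stopf("need >= 3 samples for probe selection")
  score <- abs(suppressWarnings(stats::cor(X, y)))[, 1L]
  score[is.na(score)] <- 0
  ord <- order(-score, seq_len(p))
  ord[seq_len(min(n, p))]
}
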
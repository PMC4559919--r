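#' Training hyperparameters
#'
#' @param fs Probes kept by per-gene feature selection (the most
#'   response-correlated ones), or `"all"`.  `"all"` is capped at
#'   `fs_cap` probes to bound tree-growing cost on probe-rich genes.
#' @param mtry Predictors sampled per split, or `"default"`
#'   (`max(1, floor(p/3))`).
#' @param ntree Trees per gene.
#' @param min_node_size Minimum terminal-node size.
#' @param quantiles Default prediction-interval probabilities.
#' @param seed Global seed; each feature trains with its own derived seed
#'   `derive_seed(seed, feature_id)` so results do not depend on the order
#'   in which genes are processed.
#' @param fs_cap Upper bound on probes per gene when `fs = "all"`.
#' @param log2_response Train on `log2(y + 1)` and back-transform
#'   predictions (off by default: responses are modelled on the RPKM
#'   scale they are supplied on).
#' @param pca_k Number of principal-component scores of the full probe
#'   matrix appended to every gene's predictors (0 = off).  Loadings are
#'   learned on training samples only and projected onto test samples.
#' @return A list of class `seqpred_params`.
#' @export
seqpred_params <- function(fs = "all", mtry = "default", ntree = 500,
                           min_node_size = 5, quantiles = c(0.05, 0.95),
                           seed = 1, fs_cap = 64, log2_response = FALSE,
                           pca_k = 0) {
  if (!identical(fs, "all") && (!is.numeric(fs) || fs < 1))
    stopf("fs must be a positive count or \"all\"")
  if (any(quantiles <= 0 | quantiles >= 1) ||
      is.unsorted(quantiles, strictly = TRUE))
    stopf("quantiles must be strictly increasing in (0, 1)")
  structure(list(fs = fs, mtry = mtry, ntree = as.integer(ntree),
                 min_node_size = as.integer(min_node_size),
                 quantiles = quantiles, seed = seed,
                 fs_cap = as.integer(fs_cap),
                 log2_response = isTRUE(log2_response),
                 pca_k = as.integer(pca_k)),
            class = "seqpred_params")
}

# PCA augmentation: top-k component scores of the column-centered probe
# matrix become extra shared predictors.  Returns NULL when k <= 0.
fit_pca <- function(intensities, k) {
  if (k <= 0L) return(NULL)
  Xs <- t(intensities)                       # samples x probes
  k <- min(k, nrow(Xs) - 1L, ncol(Xs) - 1L)
  pc <- stats::prcomp(Xs, center = TRUE, scale. = FALSE, rank. = k)
  list(rotation = pc$rotation, center = pc$center, k = k)
}

pca_scores <- function(pca, intensities) {
  s <- (t(intensities[rownames(pca$rotation), , drop = FALSE]) -
          rep(pca$center, each = ncol(intensities))) %*% pca$rotation
  colnames(s) <- paste0(".pc", seq_len(ncol(s)))
  s
}

#' Learn per-gene mappings from probe intensities to RNA-Seq expression
#'
#' For every feature (gene or transcript) in `map`, fits the pipeline
#' probe selection -> quantile regression forest -> out-of-bag estimation:
#' the feature's mapped probes are ranked by absolute correlation with the
#' training response, a forest is grown on the selected probes, and the
#' cross-sample correlation of OOB estimates with the training response
#' (`r_oob`) is recorded as the model-quality score.  Features with no
#' mapped probe present in the intensity matrix are skipped with a reason.
#'
#' Training inputs are expected on matched scales — typically
#' quantile-normalized RPKM responses and (optionally quantile-normalized)
#' linear-scale intensities; see [quantile_normalize()].
#'
#' @param intensities Probe intensity matrix, probes x samples (training
#'   samples in columns).
#' @param expression Expression matrix, features x samples, RPKM scale;
#'   columns must cover the intensity samples.
#' @param map Feature-to-probe map (named list of probe id vectors).
#' @param params A [seqpred_params()] object.
#' @return An object of class `seqpred`: per-feature models with forests,
#'   OOB estimates and `r_oob`, plus the training metadata needed to
#'   predict on new arrays.  Methods: `print`, `summary`, `predict`,
#'   `fitted` (OOB estimates), `residuals` (response minus OOB), `plot`.
#' @examples
#' sim <- simulate_dataset(sim_params(n_genes = 15, n_samples = 30,
#'                                    n_train = 20, seed = 2))
#' tr <- sim$truth$train
#' fit <- seqpred(sim$intensities[, tr], sim$expression[, tr], sim$map,
#'                seqpred_params(ntree = 50, seed = 2))
#' summary(fit)
#' est <- predict(fit, sim$intensities[, sim$truth$test])
#' @export
seqpred <- function(intensities, expression, map,
                    params = seqpred_params()) {
  stopifnot(inherits(params, "seqpred_params"))
  samples <- intersect(colnames(intensities), colnames(expression))
  if (length(samples) < 5L) stopf("need >= 5 shared training samples")
  Xall <- intensities[, samples, drop = FALSE]
  pca <- fit_pca(Xall, params$pca_k)
  extra <- if (is.null(pca)) NULL else pca_scores(pca, Xall)
  features <- intersect(names(map), rownames(expression))
  models <- list()
  skipped <- character(0)
  for (f in features) {
    probes <- intersect(map[[f]], rownames(Xall))
    if (!length(probes)) {
      skipped[f] <- "no mapped probes present in intensity matrix"
      next
    }
    y <- expression[f, samples]
    if (params$log2_response) y <- log2(y + 1)
    Xf <- t(Xall[probes, , drop = FALSE])
    n_keep <- if (identical(params$fs, "all")) min(length(probes), params$fs_cap)
              else min(params$fs, length(probes))
    sel <- select_probes(Xf, y, n_keep)
    fseed <- derive_seed(params$seed, f)
    Xsel <- Xf[, sel, drop = FALSE]
    if (!is.null(extra)) Xsel <- cbind(Xsel, extra)
    forest <- qr_forest(Xsel, y, ntree = params$ntree, mtry = params$mtry,
                        min_node_size = params$min_node_size, seed = fseed)
    oob <- oob_predict(forest)
    models[[f]] <- list(feature_id = f, probes = colnames(Xsel),
                        forest = forest, oob = oob,
                        r_oob = oob_correlation(oob, y), seed = fseed)
  }
  structure(list(models = models, params = params, pca = pca,
                 train_samples = samples, skipped = skipped),
            class = "seqpred")
}

#' @export
print.seqpred <- function(x, ...) {
  r <- r_oob(x)
  cat(sprintf("Probe-to-expression model: %d feature(s), %d training sample(s)\n",
              length(x$models), length(x$train_samples)))
  cat(sprintf("  trees per feature: %d, feature selection: %s\n",
              x$params$ntree, format(x$params$fs)))
  if (length(r))
    cat(sprintf("  r_oob: median %.3f, %d/%d features with r_oob > 0\n",
                stats::median(r, na.rm = TRUE), sum(r > 0, na.rm = TRUE),
                length(r)))
  if (length(x$skipped)) cat(sprintf("  skipped features: %d\n", length(x$skipped)))
  invisible(x)
}

#' @method summary seqpred
#' @export
summary.seqpred <- function(object, ...) {
  r <- r_oob(object)
  out <- list(n_features = length(object$models),
              n_train = length(object$train_samples),
              n_skipped = length(object$skipped),
              r_oob = summary(r),
              n_undefined = sum(is.na(r)),
              retained_at = vapply(c(0, .2, .4, .6),
                                   function(t) sum(r > t, na.rm = TRUE), 0))
  names(out$retained_at) <- paste0("r_oob>", c(0, .2, .4, .6))
  class(out) <- "summary.seqpred"
  out
}

#' @export
print.summary.seqpred <- function(x, ...) {
  cat(sprintf("%d feature model(s) on %d training samples (%d skipped)\n",
              x$n_features, x$n_train, x$n_skipped))
  cat("OOB cross-sample correlation (r_oob):\n")
  print(x$r_oob)
  cat(sprintf("undefined r_oob: %d\nfeatures retained at thresholds:\n",
              x$n_undefined))
  print(x$retained_at)
  invisible(x)
}

#' Per-feature OOB correlations of a fitted model
#'
#' @param object A [seqpred()] or [seqpred_isoforms()] fit.
#' @return Named numeric vector of `r_oob` values (`NA` = undefined).
#' @export
r_oob <- function(object) {
  if (inherits(object, "seqpred_multi"))
    return(unlist(lapply(object$models, `[[`, "r_oob")))
  vapply(object$models, `[[`, 0, "r_oob")
}

#' Filter trained models by OOB correlation
#'
#' Keeps features whose `r_oob` is defined and strictly greater than
#' `threshold`.  The default threshold 0 retains only genes whose OOB
#' estimates are positively correlated with the training response.
#'
#' @param object A fitted `seqpred` (or `seqpred_multi`) object.
#' @param threshold Correlation threshold in \[-1, 1\].
#' @return The fit restricted to retained features, with a `"filter"`
#'   attribute recording kept/dropped counts.
#' @export
oob_filter <- function(object, threshold = 0) {
  if (threshold < -1 || threshold > 1) stopf("threshold must lie in [-1, 1]")
  r <- vapply(object$models, function(m) {
    rr <- m$r_oob            # length > 1 for multi-response gene models
    if (all(is.na(rr))) NA_real_ else max(rr, na.rm = TRUE)
  }, 0)
  keep <- !is.na(r) & r > threshold
  out <- object
  out$models <- object$models[keep]
  attr(out, "filter") <- list(threshold = threshold,
                              kept = sum(keep), dropped = sum(!keep))
  out
}

#' Predict expression for new arrays
#'
#' Applies every retained per-feature forest to the probe intensities of
#' new samples, yielding expression estimates on the scale the model was
#' trained on (RPKM when trained on RPKM).  Optionally returns prediction
#' intervals as conditional quantiles, and can filter to well-estimated
#' features on the fly via `oob_threshold`.
#'
#' @param object A [seqpred()] fit.
#' @param intensities Probe intensity matrix, probes x samples; must be on
#'   the same scale/normalization as the training intensities.
#' @param quantiles Optional probabilities for prediction intervals.
#' @param oob_threshold Optional `r_oob` filter applied before predicting.
#' @param ... Unused.
#' @return Features x samples matrix of estimates, or, with `quantiles`, a
#'   list with elements `mean` and one matrix per quantile.
#' @export
predict.seqpred <- function(object, intensities, quantiles = NULL,
                            oob_threshold = NULL, ...) {
  if (!is.null(oob_threshold)) object <- oob_filter(object, oob_threshold)
  if (!length(object$models)) {
    warning("no features retained; returning empty matrix")
    return(matrix(0, 0, ncol(intensities),
                  dimnames = list(NULL, colnames(intensities))))
  }
  Xnew <- t(intensities)
  if (!is.null(object$pca))
    Xnew <- cbind(Xnew, pca_scores(object$pca, intensities))
  feats <- names(object$models)
  est <- matrix(NA_real_, length(feats), nrow(Xnew),
                dimnames = list(feats, rownames(Xnew)))
  qmats <- if (!is.null(quantiles))
    lapply(quantiles, function(q) est) else NULL
  for (f in feats) {
    m <- object$models[[f]]
    if (is.null(quantiles)) {
      est[f, ] <- predict(m$forest, Xnew)
    } else {
      pr <- predict(m$forest, Xnew, quantiles = quantiles)
      est[f, ] <- pr$mean
      qm <- pr$quantiles
      if (is.null(dim(qm))) qm <- matrix(qm, ncol = length(quantiles))
      for (k in seq_along(quantiles)) qmats[[k]][f, ] <- qm[, k]
    }
  }
  back <- function(m) if (object$params$log2_response) pmax(2^m - 1, 0) else m
  est <- back(est)
  attr(est, "scale_tag") <- if (object$params$log2_response) "rpkm"
                            else "normalized_rpkm"
  if (is.null(quantiles)) return(est)
  names(qmats) <- paste0("q", quantiles)
  c(list(mean = est), lapply(qmats, back))
}

#' @export
fitted.seqpred <- function(object, ...) {
  feats <- names(object$models)
  out <- matrix(NA_real_, length(feats), length(object$train_samples),
                dimnames = list(feats, object$train_samples))
  for (f in feats) out[f, ] <- object$models[[f]]$oob
  if (object$params$log2_response) out <- pmax(2^out - 1, 0)
  out
}

#' @method residuals seqpred
#' @export
residuals.seqpred <- function(object, ...) {
  feats <- names(object$models)
  out <- matrix(NA_real_, length(feats), length(object$train_samples),
                dimnames = list(feats, object$train_samples))
  for (f in feats) {
    m <- object$models[[f]]
    out[f, ] <- m$forest$y[, 1L] - m$oob
  }
  out
}

#' Plot the OOB filtering profile of a fit
#'
#' Shows the distribution of per-feature `r_oob` and, as a curve, the
#' number of features retained as the OOB-correlation threshold increases
#' — the trade-off between coverage and expected accuracy.
#'
#' @param x A [seqpred()] fit.
#' @param ... Passed to [graphics::hist()].
#' @method plot seqpred
#' @export
plot.seqpred <- function(x, ...) {
  r <- r_oob(x)
  r <- r[!is.na(r)]
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::hist(r, main = "OOB cross-sample correlation",
                 xlab = "r_oob", ...)
  th <- seq(-1, 1, by = 0.05)
  graphics::plot(th, vapply(th, function(t) sum(r > t), 0), type = "s",
                 xlab = "r_oob threshold", ylab = "features retained",
                 main = "OOB filtering")
  invisible(x)
}

#' Export the per-feature quality table
#'
#' @param object A fitted `seqpred` object.
#' @return `data.frame` with `feature_id`, `n_probes`, `r_oob`.
#' @export
r_oob_table <- function(object) {
  data.frame(feature_id = names(object$models),
             n_probes = vapply(object$models,
                               function(m) length(m$probes), 0L),
             r_oob = r_oob(object), row.names = NULL,
             stringsAsFactors = FALSE)
}
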
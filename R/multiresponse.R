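#' Learn transcript-isoform expression with multi-response forests
#'
#' Gene arrays lack dedicated isoform probe sets, but the probes tiled
#' along a gene respond to different subsets of its isoforms, so their
#' joint intensity pattern carries isoform information.  One forest is
#' grown per gene on *all* of its mapped probes (no feature selection),
#' with the gene's transcript expression vectors as a joint response:
#' splits maximize the summed variance reduction across transcripts, each
#' standardized to unit variance, and leaves store sample indices so that
#' per-transcript predictions, OOB estimates and `r_oob` are read off by
#' looking up each transcript's response at the leaf samples.  A
#' single-transcript gene reproduces the univariate [seqpred()] model
#' exactly under the same seed.
#'
#' @param intensities Probe intensities, probes x training samples.
#' @param transcripts Transcript expression matrix, transcripts x samples.
#' @param gene_transcripts Named list: gene id -> transcript ids.
#' @param map Feature-to-probe map keyed by gene id.
#' @param params A [seqpred_params()]; `fs` is ignored (all gene probes
#'   are used).
#' @return An object of class `seqpred_multi` (also `seqpred` for shared
#'   methods); each model carries a per-transcript `r_oob` vector.
#'   Transcripts with zero training variance get an undefined (`NA`)
#'   `r_oob` but the model still fits.
#' @export
seqpred_isoforms <- function(intensities, transcripts, gene_transcripts,
                             map, params = seqpred_params()) {
  stopifnot(inherits(params, "seqpred_params"))
  samples <- intersect(colnames(intensities), colnames(transcripts))
  if (length(samples) < 5L) stopf("need >= 5 shared training samples")
  Xall <- intensities[, samples, drop = FALSE]
  models <- list()
  skipped <- character(0)
  for (g in names(gene_transcripts)) {
    tx <- intersect(gene_transcripts[[g]], rownames(transcripts))
    probes <- intersect(map[[g]] %||% character(0), rownames(Xall))
    if (!length(tx) || !length(probes)) {
      skipped[g] <- "no transcripts or no mapped probes present"
      next
    }
    Y <- t(transcripts[tx, samples, drop = FALSE])
    if (params$log2_response) Y <- log2(Y + 1)
    fseed <- derive_seed(params$seed, g)
    forest <- qr_forest(t(Xall[probes, , drop = FALSE]), Y,
                        ntree = params$ntree, mtry = params$mtry,
                        min_node_size = params$min_node_size, seed = fseed)
    oob <- oob_predict(forest)
    if (is.null(dim(oob))) oob <- matrix(oob, ncol = 1L,
                                         dimnames = list(samples, tx))
    r <- vapply(seq_along(tx),
                function(j) oob_correlation(oob[, j], Y[, j]), 0)
    names(r) <- tx
    models[[g]] <- list(feature_id = g, transcripts = tx, probes = probes,
                        forest = forest, oob = oob, r_oob = r, seed = fseed)
  }
  structure(list(models = models, params = params, pca = NULL,
                 train_samples = samples, skipped = skipped),
            class = c("seqpred_multi", "seqpred"))
}

#' @export
print.seqpred_multi <- function(x, ...) {
  r <- r_oob(x)
  cat(sprintf("Multi-response isoform model: %d gene(s), %d transcript(s), %d training sample(s)\n",
              length(x$models), length(r), length(x$train_samples)))
  if (length(r))
    cat(sprintf("  per-transcript r_oob: median %.3f, %d/%d > 0\n",
                stats::median(r, na.rm = TRUE),
                sum(r > 0, na.rm = TRUE), length(r)))
  invisible(x)
}

#' Predict transcript expression from new arrays
#'
#' @param object A [seqpred_isoforms()] fit.
#' @param intensities Probe intensities, probes x samples.
#' @param quantiles Optional interval probabilities.
#' @param ... Unused.
#' @return Transcripts x samples matrix (or a list with `mean` and per-
#'   quantile matrices).
#' @export
predict.seqpred_multi <- function(object, intensities, quantiles = NULL, ...) {
  Xnew <- t(intensities)
  tx_all <- unlist(lapply(object$models, `[[`, "transcripts"),
                   use.names = FALSE)
  est <- matrix(NA_real_, length(tx_all), nrow(Xnew),
                dimnames = list(tx_all, rownames(Xnew)))
  qmats <- if (!is.null(quantiles)) lapply(quantiles, function(q) est)
  for (m in object$models) {
    if (is.null(quantiles)) {
      pr <- predict(m$forest, Xnew)
      if (is.null(dim(pr))) pr <- matrix(pr, ncol = 1L)
      est[m$transcripts, ] <- t(pr)
    } else {
      pr <- predict(m$forest, Xnew, quantiles = quantiles)
      mn <- pr$mean
      if (is.null(dim(mn))) mn <- matrix(mn, ncol = 1L)
      est[m$transcripts, ] <- t(mn)
      qa <- pr$quantiles
      if (length(dim(qa)) < 3L)
        qa <- array(qa, c(nrow(Xnew), length(quantiles), 1L))
      for (k in seq_along(quantiles))
        qmats[[k]][m$transcripts, ] <- t(qa[, k, , drop = TRUE])
    }
  }
  back <- function(x) if (object$params$log2_response) pmax(2^x - 1, 0) else x
  est <- back(est)
  if (is.null(quantiles)) return(est)
  names(qmats) <- paste0("q", quantiles)
  c(list(mean = est), lapply(qmats, back))
}
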
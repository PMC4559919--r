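#' Parameters for the paired array/RNA-Seq simulator
#'
#' The generator emulates the structure the learner assumes: a latent
#' expression level per gene and sample drives both (i) probe fluorescence
#' through a saturating, affinity-biased, noisy hybridization response and
#' (ii) RNA-Seq read counts through multinomial-like Poisson sampling,
#' converted to RPKM.
#'
#' Defaults describe the reference study scenario used throughout the
#' package's own evaluation: 200 genes with 8 probes each, 60 samples of
#' which 40 train, saturating probes, moderate hybridization noise, and a
#' sequencing depth scaled to the 200-gene universe so that low-expression
#' genes show appreciable counting noise.
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Probes per gene.
#' @param n_samples,n_train Total and training sample counts
#'   (`n_train < n_samples`).
#' @param isoforms_per_gene 1 for gene-level data; >= 2 adds transcript
#'   isoforms with isoform-specific and shared probes.
#' @param log_mean_range Range of per-gene log-normal location `mu_i`
#'   (latent expression `x ~ LogNormal(mu_i, sigma_i)`).
#' @param sigma_range Range of per-gene cross-sample log-sd `sigma_i`;
#'   a wide range yields heterogeneous per-gene signal strength.
#' @param affinity_sd Log-scale sd of per-probe affinity `a_p`.
#' @param background_sd Log-scale sd of an optional additive per-probe
#'   background level (0 disables the term, the default).
#' @param k_range Range (log-uniform) of the per-probe half-saturation
#'   constant `K_p`, in expression units; intensities follow
#'   `I = scale * exp(a_p) * x / (x + K_p) * exp(eps)`.
#' @param noise_sd Log-scale sd of the multiplicative intensity noise `eps`.
#' @param depth Total mapped reads per sample.
#' @param length_range Range of gene lengths in kb.
#' @param intensity_scale Overall fluorescence amplitude.
#' @param de_frac Fraction of genes with a planted expression shift
#'   between the two sample groups (first vs second half of samples).
#' @param de_lfc Absolute log fold change of planted genes (random sign).
#' @param dedicated_probes With isoforms: give each isoform
#'   `dedicated_per_isoform` probes of its own (remaining probes respond
#'   to the sum of all isoforms, like probes in constitutive exons).  With
#'   `FALSE` all probes are shared and isoform recovery is impossible by
#'   construction; the truth is flagged non-identifiable.
#' @param dedicated_per_isoform Isoform-specific probes per isoform
#'   (gene arrays typically tile several probe sets across
#'   alternatively-included exons).
#' @param seed Master seed; every stage draws from a named substream
#'   derived from it, so stages can be varied independently.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 200, probes_per_gene = 8, n_samples = 60,
                       n_train = 40, isoforms_per_gene = 1,
                       log_mean_range = c(log(0.5), log(200)),
                       sigma_range = c(0.3, 1.2), affinity_sd = 0.7,
                       background_sd = 0, k_range = c(20, 2000),
                       noise_sd = 0.25, depth = 3e5,
                       length_range = c(0.5, 8), intensity_scale = 3000,
                       de_frac = 0, de_lfc = log(3),
                       dedicated_probes = TRUE, dedicated_per_isoform = 1,
                       seed = 1) {
  if (n_train >= n_samples) stopf("n_train must be smaller than n_samples")
  if (min(n_genes, probes_per_gene, n_samples, n_train,
          isoforms_per_gene) < 1) stopf("all counts must be >= 1")
  if (min(affinity_sd, background_sd, noise_sd) < 0) stopf("sds must be >= 0")
  if (isoforms_per_gene > 1 && dedicated_probes &&
      probes_per_gene < isoforms_per_gene * dedicated_per_isoform)
    stopf("need probes_per_gene >= isoforms_per_gene * dedicated_per_isoform")
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  set.seed(derive_seed(seed, name))
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  expr
}

#' Simulate a paired probe-intensity / RNA-Seq dataset
#'
#' Generates, from a single seed, (i) latent expression
#' `x_is ~ LogNormal(mu_i, sigma_i)`, (ii) probe intensities
#' `I_ps = scale * exp(a_p) * x_is / (x_is + K_p) * exp(eps)` with
#' `eps ~ N(0, noise_sd)` for the probes of gene i — a Langmuir-type
#' saturating response whose high-end compression reproduces the
#' underestimation of highly expressed genes seen on real arrays — and
#' (iii) read counts `c_is ~ Poisson(depth * x_is * len_i / sum_j x_js
#' len_j)` converted to `RPKM = c / (len_kb * depth / 1e6)`.  With
#' `isoforms_per_gene >= 2` each probe covers a declared isoform subset
#' and its driving abundance is the summed expression of covered
#' isoforms; gene counts are the sum of isoform counts.
#'
#' @param params A [sim_params()] object.
#' @return List with `intensities` (probes x samples), `expression`
#'   (genes x samples, RPKM), `transcripts` (transcripts x samples RPKM,
#'   or NULL), `map` (gene -> probes), `transcript_map` (gene ->
#'   transcript ids, or NULL) and `truth` (latent matrices, truth-scale expected RPKM, per-probe
#'   parameters, probe-isoform coverage, train/test split, planted DE
#'   genes, groups, the params).
#' @export
simulate_dataset <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  p <- params
  genes <- sprintf("g%04d", seq_len(p$n_genes))
  samples <- sprintf("s%03d", seq_len(p$n_samples))
  K <- p$isoforms_per_gene
  tx <- if (K > 1) as.vector(t(outer(genes, seq_len(K), paste, sep = ".t")))

  gene_par <- with_substream(p$seed, "genes", {
    data.frame(gene = genes,
               mu = runif(p$n_genes, p$log_mean_range[1], p$log_mean_range[2]),
               sigma = runif(p$n_genes, p$sigma_range[1], p$sigma_range[2]),
               len_kb = runif(p$n_genes, p$length_range[1], p$length_range[2]))
  })

  # latent expression; isoforms split the gene between them
  n_units <- p$n_genes * K
  latent_units <- with_substream(p$seed, "latent", {
    mu_u <- rep(gene_par$mu, each = K) - log(K)
    sd_u <- rep(gene_par$sigma, each = K)
    matrix(rlnorm(n_units * p$n_samples, mu_u, sd_u), n_units, p$n_samples,
           dimnames = list(if (K > 1) tx else genes, samples))
  })

  # planted group effect on the latent scale
  groups <- rep(c("A", "B"), c(ceiling(p$n_samples / 2),
                               floor(p$n_samples / 2)))
  names(groups) <- samples
  de_genes <- character(0)
  if (p$de_frac > 0) {
    eff <- with_substream(p$seed, "de", {
      idx <- sample(p$n_genes, round(p$de_frac * p$n_genes))
      list(idx = idx, sign = sample(c(-1, 1), length(idx), replace = TRUE))
    })
    de_genes <- genes[eff$idx]
    urow <- rep(seq_len(p$n_genes), each = K)
    for (j in seq_along(eff$idx)) {
      rows <- which(urow == eff$idx[j])
      latent_units[rows, groups == "B"] <-
        latent_units[rows, groups == "B"] * exp(eff$sign[j] * p$de_lfc)
    }
  }
  latent_gene <- if (K > 1)
    rowsum(latent_units, rep(genes, each = K), reorder = FALSE)
  else latent_units

  # probes: ids, affinities, saturation constants, isoform coverage
  probe_gene <- rep(genes, each = p$probes_per_gene)
  probe_ids <- paste0(probe_gene, "_p",
                      rep(seq_len(p$probes_per_gene), times = p$n_genes))
  probe_par <- with_substream(p$seed, "probes", {
    data.frame(probe = probe_ids, gene = probe_gene,
               a = rnorm(length(probe_ids), 0, p$affinity_sd),
               b = if (p$background_sd > 0)
                 rnorm(length(probe_ids), 0, p$background_sd) else
                   rep(-Inf, length(probe_ids)),
               K = exp(runif(length(probe_ids), log(p$k_range[1]),
                             log(p$k_range[2]))))
  })
  within_gene <- rep(seq_len(p$probes_per_gene), times = p$n_genes)
  coverage <- NULL
  if (K > 1) {
    # first dedicated_per_isoform * K probes are isoform-specific
    # (cycling through isoforms), the rest respond to all isoforms
    nd <- p$dedicated_per_isoform * K
    coverage <- lapply(seq_along(probe_ids), function(i) {
      if (p$dedicated_probes && within_gene[i] <= nd)
        (within_gene[i] - 1L) %% K + 1L
      else seq_len(K)
    })
    names(coverage) <- probe_ids
  }

  # driving abundance per probe
  drive <- if (K > 1) {
    t(vapply(seq_along(probe_ids), function(i) {
      rows <- (match(probe_gene[i], genes) - 1L) * K + coverage[[i]]
      colSums(latent_units[rows, , drop = FALSE])
    }, numeric(p$n_samples)))
  } else latent_gene[probe_gene, , drop = FALSE]

  intensities <- with_substream(p$seed, "noise", {
    eps <- matrix(rnorm(length(probe_ids) * p$n_samples, 0, p$noise_sd),
                  length(probe_ids), p$n_samples)
    bg <- ifelse(is.finite(probe_par$b), exp(probe_par$b), 0)
    p$intensity_scale *
      (exp(probe_par$a) * drive / (drive + probe_par$K) * exp(eps) + bg)
  })
  dimnames(intensities) <- list(probe_ids, samples)

  # sequencing: Poisson counts at unit (isoform) level, RPKM conversion
  len_units <- rep(gene_par$len_kb, each = K)
  counts <- with_substream(p$seed, "counts", {
    wt <- latent_units * len_units
    lam <- sweep(wt, 2L, colSums(wt), "/") * p$depth
    matrix(rpois(length(lam), lam), nrow(lam), ncol(lam))
  })
  rpkm_units <- counts / (len_units * p$depth / 1e6)
  dimnames(rpkm_units) <- dimnames(latent_units)
  # truth-scale RPKM: expected RPKM given the latent expression (no
  # counting noise); E[c]/(len * depth/1e6) = 1e6 * x / sum_j(x_j len_j)
  wt_all <- latent_units * len_units
  rpkm_expected_units <- sweep(latent_units, 2L, colSums(wt_all), "/") * 1e6
  rpkm_expected <- if (K > 1)
    rowsum(rpkm_expected_units, rep(genes, each = K), reorder = FALSE)
  else rpkm_expected_units
  dimnames(rpkm_expected) <- list(genes, samples)
  expression <- if (K > 1) {
    gc <- rowsum(counts, rep(genes, each = K), reorder = FALSE)
    gm <- gc / (gene_par$len_kb * p$depth / 1e6)
    dimnames(gm) <- list(genes, samples)
    gm
  } else rpkm_units
  attr(expression, "scale_tag") <- "rpkm"

  split <- split_train_test(samples, p$n_train / p$n_samples,
                            seed = derive_seed(p$seed, "split"))

  map <- split(probe_ids, factor(probe_gene, levels = genes))
  map <- check_probe_map(lapply(map, as.character))

  transcripts <- NULL
  transcript_map <- NULL
  if (K > 1) {
    transcripts <- rpkm_units
    attr(transcripts, "scale_tag") <- "rpkm"
    transcript_map <- split(tx, factor(rep(genes, each = K), levels = genes))
  }

  list(intensities = intensities, expression = expression,
       transcripts = transcripts, map = map,
       transcript_map = transcript_map,
       truth = list(latent = latent_gene,
                    latent_transcripts = if (K > 1) latent_units,
                    rpkm_expected = rpkm_expected,
                    gene_params = gene_par,
                    probe_params = probe_par, coverage = coverage,
                    identifiable = K == 1 || p$dedicated_probes,
                    train = split$train, test = split$test,
                    groups = groups, de_genes = de_genes, params = p))
}

#' Split samples into training and test sets
#'
#' Draws `round(fraction * n)` samples without replacement as the training
#' set, reproducibly from `seed`; the split is disjoint and exhaustive.
#'
#' @param sample_ids Character vector of sample ids.
#' @param fraction Training fraction in (0, 1).
#' @param seed Integer seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_train_test <- function(sample_ids, fraction, seed = 1) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must lie in (0, 1)")
  n <- length(sample_ids)
  k <- round(fraction * n)
  if (k < 5L) stopf("training set of %d samples is too small (< 5)", k)
  train <- with_substream(seed, "train_test",
                          sort(sample(n, k)))
  list(train = sample_ids[train], test = sample_ids[-train])
}

#' Simulate a two-tissue mixture titration experiment
#'
#' Mirrors the classic array benchmark in which total RNA from two tissues
#' is mixed in known proportions: the latent profile of a mixture column
#' is `p * pure_A + (1 - p) * pure_B` per gene.  Biological replicates
#' jitter the pure profiles (log-normal, `bio_jitter_sd`) before mixing;
#' technical replicates re-draw intensity noise only.  The default design
#' (nine ratios, three biological replicates at 0.5:0.5, three technical
#' replicates each) yields 33 arrays.
#'
#' @param pure_profiles Genes x 2 matrix; column 1 = tissue A (e.g. heart),
#'   column 2 = tissue B (e.g. brain).
#' @param design `data.frame` with columns `proportion_A`, `n_bio`,
#'   `n_tech`; defaults to the nine-ratio titration above.
#' @param map Feature-to-probe map used to lay out probes; defaults to
#'   `probes_per_gene` fresh probes per gene.
#' @param probes_per_gene,affinity_sd,k_range,noise_sd,intensity_scale
#'   Probe model parameters as in [sim_params()].
#' @param bio_jitter_sd Log-scale sd of the biological-replicate jitter.
#' @param seed Master seed.
#' @return List with `intensities` (probes x arrays), `latent` (genes x
#'   arrays), `metadata` (`sample_id`, `proportion_A`, `bio_rep`,
#'   `tech_rep`), `map` and `probe_params`.
#' @export
simulate_mixture <- function(pure_profiles,
                             design = data.frame(
                               proportion_A = c(1, 0.95, 0.9, 0.75, 0.5,
                                                0.25, 0.1, 0.05, 0),
                               n_bio = c(1, 1, 1, 1, 3, 1, 1, 1, 1),
                               n_tech = 3),
                             probes_per_gene = 4, affinity_sd = 0.7,
                             k_range = c(20, 2000), noise_sd = 0.25,
                             intensity_scale = 3000, bio_jitter_sd = 0.1,
                             seed = 1) {
  if (any(design$proportion_A < 0 | design$proportion_A > 1))
    stopf("proportions must lie in [0, 1]")
  genes <- rownames(pure_profiles) %||% sprintf("g%04d", seq_len(nrow(pure_profiles)))
  ng <- length(genes)
  probe_ids <- paste0(rep(genes, each = probes_per_gene), "_p",
                      rep(seq_len(probes_per_gene), times = ng))
  probe_par <- with_substream(seed, "mix_probes", {
    data.frame(probe = probe_ids, gene = rep(genes, each = probes_per_gene),
               a = rnorm(length(probe_ids), 0, affinity_sd),
               K = exp(runif(length(probe_ids), log(k_range[1]),
                             log(k_range[2]))))
  })
  meta <- do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    expand.grid(tech_rep = seq_len(design$n_tech[i]),
                bio_rep = seq_len(design$n_bio[i]),
                proportion_A = design$proportion_A[i])
  }))
  meta <- meta[, c("proportion_A", "bio_rep", "tech_rep")]
  meta$sample_id <- sprintf("mix%02d_p%03d_b%d_t%d", seq_len(nrow(meta)),
                            round(100 * meta$proportion_A), meta$bio_rep,
                            meta$tech_rep)
  # biological latent profile per (ratio, bio rep), shared by tech reps
  bio_key <- paste(meta$proportion_A, meta$bio_rep)
  ukey <- unique(bio_key)
  latent_by_bio <- with_substream(seed, "mix_bio", {
    sapply(ukey, function(k) {
      i <- which(bio_key == k)[1L]
      pA <- meta$proportion_A[i]
      jitter <- if (bio_jitter_sd > 0)
        matrix(rlnorm(2 * ng, 0, bio_jitter_sd), ng, 2) else matrix(1, ng, 2)
      pA * pure_profiles[, 1L] * jitter[, 1L] +
        (1 - pA) * pure_profiles[, 2L] * jitter[, 2L]
    })
  })
  latent <- latent_by_bio[, match(bio_key, ukey), drop = FALSE]
  dimnames(latent) <- list(genes, meta$sample_id)
  drive <- latent[probe_par$gene, , drop = FALSE]
  intensities <- with_substream(seed, "mix_noise", {
    eps <- matrix(rnorm(length(probe_ids) * nrow(meta), 0, noise_sd),
                  length(probe_ids), nrow(meta))
    intensity_scale * exp(probe_par$a) * drive / (drive + probe_par$K) *
      exp(eps)
  })
  dimnames(intensities) <- list(probe_ids, meta$sample_id)
  map <- split(probe_ids, factor(probe_par$gene, levels = genes))
  list(intensities = intensities, latent = latent, metadata = meta,
       map = check_probe_map(lapply(map, as.character)),
       probe_params = probe_par)
}
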
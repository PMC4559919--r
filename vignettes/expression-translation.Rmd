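---
title: "Translating microarray probe intensities into RNA-Seq expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating microarray probe intensities into RNA-Seq expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqpred)
```

## The problem

Single-channel expression microarrays report, per gene, a set of probe
fluorescence intensities.  Classical summarization (median polish as in
RMA, or PLIER) compresses those probes into one number per gene and
sample, but the result lives on an arbitrary log-ish scale: values are
comparable across samples for one gene, not across genes, and not
against RNA-Seq.  When paired microarray and RNA-Seq measurements exist
for a panel of training samples, a different route opens: treat the
probe intensities as predictors and the RNA-Seq expression estimate
(RPKM) as the response, and learn the mapping per gene.  Arrays profiled
later — including archived experiments with no RNA available — can then
be translated onto the absolute RPKM scale, with per-gene quality
estimates and prediction intervals.

`seqpred` implements this translation with per-gene quantile regression
forests, together with everything the workflow needs around it: building
feature-to-probe maps from genomic coordinates, translating probes
across array generations, quantile normalization, a median-polish
baseline, the evaluation statistics used to compare methods, and a
synthetic paired-data generator so the whole pipeline is testable
without external downloads.

## The model

For gene $g$ with probes $p_1,\dots,p_m$ and training samples
$1,\dots,n$, the forest is grown on predictor rows
$x_i = (I_{p_1 i}, \dots, I_{p_m i})$ with response $y_i$, the
(quantile-normalized) RPKM value.  Each of `ntree` trees is grown on a
bootstrap sample of size $n$; nodes are split by variance reduction over
`mtry` randomly chosen predictors and splitting stops when a child would
fall below `min_node_size` samples.  Leaves retain the distinct in-bag
training-sample indices rather than just a mean, which makes the forest
an estimator of the conditional distribution: a query $x$ induces
weights over training samples,

$$ w_i(x) \;=\; \frac{1}{T}\sum_{t=1}^{T}
   \frac{\mathbf 1\{i \in \ell_t(x)\}}{|\ell_t(x)|}, $$

where $\ell_t(x)$ is the (distinct in-bag) support of the leaf $x$
reaches in tree $t$.  The point estimate is the weighted mean
$\sum_i w_i(x)\, y_i$, and the $q$-quantile is the smallest $y_i$ whose
cumulative weight reaches $q$ — the prediction interval comes free.
Weights are non-negative and sum to one, so predictions are always
convex combinations of training responses; the method interpolates and
never extrapolates beyond the observed response range.  That is the
correct behavior for saturated probes (which genuinely carry no signal
at the top of the range) but it means the extreme top of a test sample
is shrunk toward the training distribution.

Before growing the forest, a feature-selection step ranks the gene's
probes by the absolute Pearson correlation of their intensities with the
response and keeps the strongest `fs` of them.  Correlation strength
rather than sign is used because trees handle decreasing monotone
relations as easily as increasing ones.

### Out-of-bag quality and filtering

Each training sample is out-of-bag (OOB) for roughly $e^{-1}$ of the
trees; predicting it from only those trees gives an internal
cross-validated estimate.  The Pearson correlation `r_oob` between OOB
estimates and the training response, computed per gene, anticipates how
well that gene's model will track held-out samples, and is the filter
statistic: `oob_filter(fit, t)` retains genes with `r_oob` strictly
greater than `t`.  The default threshold 0 keeps genes whose models
carry any positive signal.

### Multi-response transcript models

Transcript isoforms are handled by replacing the scalar response with
the matrix of the gene's transcript RPKMs.  One forest per gene is grown
on *all* of the gene's probes (no selection); split scores sum the
variance reduction across transcripts, each standardized to unit
variance so abundant isoforms do not dominate.  Leaves store sample
indices only, so per-transcript predictions, OOB estimates and `r_oob`
come from looking up each transcript's response at the leaf samples.
With a single transcript the procedure reduces exactly — same seed, same
trees — to the univariate model, which the tests assert.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `fs` | `"all"` (capped at 64) | probes kept per gene by feature selection |
| `mtry` | `max(1, floor(p/3))` | predictors sampled per split |
| `ntree` | 500 | trees per gene |
| `min_node_size` | 5 | minimal terminal-node size (samples) |
| `quantiles` | 0.05, 0.95 | prediction-interval probabilities |
| `pca_k` | 0 | global PC scores appended as shared predictors |
| `log2_response` | off | train on `log2(y+1)`, back-transform predictions |

The optimal `fs`/`mtry`/`ntree` combination depends on the dataset and
should be chosen by the mean `r_oob` over genes, the same internal
statistic used for filtering — this is the tuning criterion the method
is built around, and it requires no extra held-out data.  On the
package's own synthetic scenarios, tuning by mean `r_oob` favors
`mtry` equal to the full probe set and small terminal nodes
(`min_node_size` 1–2); the package defaults stay at the conservative
regression-forest conventions (`p/3`, 5) because they are robust
across data sizes.  `log2_response` is off by default: responses are
modelled on the scale they are supplied on, and the within-sample slope
claims below are on that scale.  (Back-transformed log-scale forests
systematically underestimate large values, which is why the linear
response is the default despite RPKM's skewness.)

Reproducibility: each gene's forest is seeded by a deterministic hash of
the global seed and the feature id, so results are invariant to the
order in which genes are processed, and refitting any single gene
reproduces its model exactly.  The forest RNG is a private Park–Miller
stream; fits neither read nor disturb R's RNG state.

## Normalization

Quantile normalization maps each column's ranks onto a reference
distribution (ties receive the average of the tied reference positions).
Two modes matter in this workflow:

* **frozen** — the reference is the mean of order statistics of the
  *training* response columns; test predictions and any later data are
  projected onto it.  No information flows from test to train.  This is
  the default for `predict`-time use.
* **joint** — training and new columns are pooled and normalized
  together.  This mirrors the protocol used when applying a trained
  model to archived samples from another platform, at the cost of mild
  train/test leakage; it is available by flag.

Responses (RPKM) and predictors (intensities) are always normalized
against separate references — their units differ.

Downstream comparisons (correlation reports, within-sample slopes, DE
ranking) are computed on quantile-normalized estimates, matching the
standard practice of normalizing all methods' outputs before comparing
them.  The within-sample slope of raw forest predictions is lower than
that of their QN projection because forest means cannot reach past the
training response range at the extreme top of a sample.

## The synthetic generator

`simulate_dataset()` draws, from a single seed split into named
substreams (genes, latent, probes, noise, counts, split, de):

* latent expression $x_{is} \sim \mathrm{LogNormal}(\mu_i, \sigma_i)$,
  with per-gene $\mu_i$ uniform on $[\log 0.5, \log 200]$ and
  $\sigma_i$ uniform on $[0.3, 1.2]$ — bulk tissue panels show exactly
  this spread of cross-sample variability;
* probe intensities
  $I_{ps} = A\, e^{a_p}\, \frac{x_{is}}{x_{is} + K_p}\, e^{\varepsilon}$,
  a Langmuir-type saturating hybridization response with log-normal
  probe affinities $a_p$ ($\mathrm{sd}=0.7$), half-saturation constants
  $K_p$ log-uniform on $[20, 2000]$ expression units, and multiplicative
  noise $\varepsilon \sim N(0, 0.25)$.  The saturation reproduces the
  hallmark underestimation of highly expressed genes on arrays;
* read counts $c_{is} \sim \mathrm{Poisson}\!\left(D\,
  \frac{x_{is}\ell_i}{\sum_j x_{js}\ell_j}\right)$ with gene lengths
  $\ell_i$ uniform on $[0.5, 8]$ kb, converted to RPKM.  The default
  depth $D = 3\times10^5$ is scaled to the 200-gene universe so that
  low-expression genes show the counting noise a genome-wide library
  shows at typical depths.

Isoform mode gives each of $K$ isoforms per gene its own latent series
(splitting the gene's mean), declares a per-probe isoform coverage set
— `dedicated_per_isoform` probes specific to each isoform, the rest
responding to the isoform sum, as probes in constitutive exons do — and
emits transcript-level RPKM whose per-gene sum equals the gene RPKM
exactly.  An all-shared design is refused no information about isoforms
and is flagged non-identifiable rather than silently generated.

`simulate_mixture()` reproduces the classic two-tissue titration
benchmark: nine mixing ratios (1:0, 0.95:0.05, 0.9:0.1, 0.75:0.25,
0.5:0.5 with three biological replicates, 0.25:0.75, 0.1:0.9, 0.05:0.95,
0:1), three technical replicates each — 33 arrays.  Biological
replicates jitter the pure profiles before mixing; technical replicates
redraw intensity noise only.

**What the generator does not emulate:** cross-hybridization between
genes, probe-sequence (GC) effects, batch and scanner effects,
within-platform probe-set redundancy, and RNA-Seq mapping biases.
Passing the package's tests therefore shows the machinery is correct
and the method behaves as designed under its own assumptions — it does
not certify performance on any particular real dataset.

## Benchmark scenarios

The test suite and `scripts/acceptance.R` evaluate fixed scenarios,
sized to run on one CPU in minutes:

* **reference** — the generator defaults (200 genes × 8 probes, 60
  samples, 40 train), where forest translation is compared against
  median-polish summarization on mean cross-sample correlation with the
  latent truth (5 seeds), on the median within-sample slope of QN'd
  predictions against test RPKM, and on median absolute relative error;
* **heterogeneous** — $\sigma_i \in [0.05, 1.0]$ and probe noise 0.5,
  spanning undetectable to strong per-gene signal, used to check that
  `r_oob` predicts test-set accuracy and that OOB filtering raises the
  retained set's accuracy monotonically over thresholds 0–0.6;
* **isoform** — 60 two-isoform genes, two dedicated probes per isoform
  plus four shared, $\sigma_i \in [0.5, 1.0]$, 100 training samples.
  Transcripts must carry appreciable cross-sample variation here: a
  transcript that barely varies cannot show high cross-sample
  correlation for any method, so including such transcripts would test
  the generator, not the model;
* **differential expression** — 300 genes, 10% with a planted two-fold
  group shift, 40 training and 40 test samples over two groups; the
  rankings by Welch-t q-value from forest estimates and from
  median-polish output are each compared with the truth-based ranking
  via the cumulative Jaccard index at the planted-gene count;
* **interval calibration** — a homoscedastic nonlinear regression with
  200 training points, where the empirical coverage of the
  [0.05, 0.95] interval is checked on 300 held-out points.

## Numerical and design choices

* **Splits and ties.**  Candidate thresholds are midpoints between
  consecutive distinct values; the best split maximizes variance
  reduction, with exact ties broken toward the lowest predictor index
  and then the lowest threshold, so trees are fully deterministic.
* **Weight convention.**  Leaves store the distinct in-bag support, and
  leaf means average over that support; this is the convention under
  which the query weights $w_i(x)$ sum to exactly one.
* **Degenerate inputs.**  A constant response yields stump trees (the
  prediction is the constant) rather than an error.  A transcript with
  zero training variance gets an undefined `r_oob` but the gene's model
  still fits.  Correlations of constant vectors are reported `NA` and
  excluded from means with counts, never coerced to zero.
* **Point estimate.**  The forest mean, not the 0.5 quantile: intervals
  are the quantile machinery's contribution, while the point estimate
  should match a plain regression forest.
* **Median polish** runs until the change in the sum of absolute
  residuals drops below `tol` (default 0.01, `max_iter` 10, the classic
  settings); the decomposition reconstructs the input exactly at every
  iteration.  Inputs are `log2(x + 1)`; the offset guards zero
  intensities.
* **DE statistics.**  Welch t-tests (robust to unequal group variances),
  Benjamini–Hochberg adjustment as the q-value, and a fully specified
  rank (q, then p, then feature id).  Lin's concordance coefficient uses
  population moments; the cumulative Jaccard curve is computed
  incrementally in O(N).
* **Probe mapping.**  Overlap means ≥ 1 shared base, strand-blind (the
  `bedtools intersect` default); a probe set overlapping several genes
  is assigned to all of them unless `drop_multi_feature` is set, since
  coordinate overlap alone cannot adjudicate ownership.  Cross-platform
  translation keeps a probe only with 100% alignment identity and a
  best-match pairing by default.  The exonic filter treats the probe-set
  interval as a proxy for its probes' alignments — per-probe alignments
  are upstream of this package — which is a documented approximation.
* **Missing values** are rejected at the interface: forests and
  quantile normalization as specified assume complete matrices, so
  imputation or dropping has to happen upstream, explicitly.

## Known limitations

* Forest predictions cannot exceed the training response range, so the
  very top of a test sample's distribution is compressed; downstream
  analyses should use the QN'd predictions (the package's evaluation
  protocol does).
* `r_oob` is itself an estimate; at small training sizes it is noisy
  and the OOB filter's retained set fluctuates near the threshold.
* The exonic probe-set filter works at probe-set, not probe,
  resolution.
* Cross-platform translation drops untranslatable probes silently into
  a report attribute; genes that lose all probes disappear from the
  translated map, and downstream code must consult
  `attr(map, "dropped_features")`.
* Median polish is the only built-in summarization baseline; PLIER's
  multiplicative model is not reimplemented.
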
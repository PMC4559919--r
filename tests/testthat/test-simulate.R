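test_that("the generator is bit-reproducible from its seed", {
  a <- simulate_dataset(sim_params(n_genes = 8, n_samples = 20, n_train = 12,
                                   seed = 33))
  b <- simulate_dataset(sim_params(n_genes = 8, n_samples = 20, n_train = 12,
                                   seed = 33))
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_dataset(sim_params(n_genes = 8, n_samples = 20, n_train = 12,
                                   seed = 34))
  expect_false(identical(a$intensities, c$intensities))
})

test_that("the noiseless linear regime is perfectly rank-correlated", {
  sim <- simulate_dataset(sim_params(n_genes = 10, probes_per_gene = 1,
                                     n_samples = 25, n_train = 12,
                                     noise_sd = 0, k_range = c(1e8, 1e9),
                                     seed = 1))
  for (g in rownames(sim$truth$latent)) {
    p <- sim$map[[g]]
    expect_equal(cor(sim$intensities[p, ], sim$truth$latent[g, ],
                     method = "spearman"), 1)
  }
})

test_that("intensities increase in expression and saturate at the amplitude", {
  sim <- simulate_dataset(sim_params(n_genes = 5, probes_per_gene = 2,
                                     n_samples = 40, n_train = 20,
                                     noise_sd = 0, seed = 2))
  pp <- sim$truth$probe_params
  for (i in seq_len(nrow(pp))) {
    x <- sim$truth$latent[pp$gene[i], ]
    I <- sim$intensities[pp$probe[i], ]
    expect_true(all(diff(I[order(x)]) > 0))
    expect_true(all(I < 3000 * exp(pp$a[i])))
  }
})

test_that("deep sequencing removes counting noise from RPKM", {
  # law-of-large-numbers check: at depth 1e8 the observed RPKM converges
  # to the truth-scale expected RPKM (the latent itself differs from
  # RPKM by the per-sample compositional denominator)
  sim <- simulate_dataset(sim_params(n_genes = 100, n_samples = 50,
                                     n_train = 30, depth = 1e8, seed = 3))
  r <- vapply(rownames(sim$expression), function(g)
    cor(sim$expression[g, ], sim$truth$rpkm_expected[g, ]), 0)
  expect_true(all(r > 0.99))
  shallow <- simulate_dataset(sim_params(n_genes = 100, n_samples = 50,
                                         n_train = 30, depth = 2e4,
                                         seed = 3))
  r2 <- vapply(rownames(shallow$expression), function(g)
    suppressWarnings(cor(shallow$expression[g, ],
                         shallow$truth$rpkm_expected[g, ])), 0)
  expect_lt(mean(r2, na.rm = TRUE), mean(r))
})

test_that("RPKM column sums scale with the construction", {
  p <- sim_params(n_genes = 50, n_samples = 10, n_train = 6, seed = 4)
  sim <- simulate_dataset(p)
  # total counts per sample concentrate around the nominal depth
  counts <- sweep(sim$expression, 1,
                  sim$truth$gene_params$len_kb * p$depth / 1e6, "*")
  expect_equal(unname(colSums(counts)), rep(p$depth, 10), tolerance = 0.01)
})

test_that("train/test splits are disjoint, exhaustive and seed-stable", {
  ids <- sprintf("s%03d", 1:716)
  sp <- split_train_test(ids, 146 / 716, seed = 10)
  expect_length(sp$train, 146)
  expect_length(sp$test, 570)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), ids)
  sp2 <- split_train_test(ids, 146 / 716, seed = 10)
  expect_identical(sp, sp2)
  diff_seen <- any(vapply(1:20, function(s)
    !identical(split_train_test(ids, 0.5, seed = s)$train, sp$train), TRUE))
  expect_true(diff_seen)
  expect_identical(lengths(split_train_test(letters[1:10], 0.5, seed = 1)),
                   c(train = 5L, test = 5L))
  expect_error(split_train_test(letters[1:6], 0.2), "too small")
})

test_that("isoform RPKM sums to gene RPKM and carries dedicated probes", {
  sim <- simulate_dataset(sim_params(n_genes = 6, probes_per_gene = 6,
                                     n_samples = 20, n_train = 10,
                                     isoforms_per_gene = 2,
                                     dedicated_per_isoform = 2, seed = 5))
  g <- rownames(sim$expression)[1]
  tx <- sim$transcript_map[[g]]
  expect_equal(colSums(sim$transcripts[tx, ]), sim$expression[g, ])
  expect_true(sim$truth$identifiable)
  cov <- sim$truth$coverage[sim$map[[g]]]
  expect_equal(sum(lengths(cov) == 1), 4)   # 2 dedicated per isoform
  expect_equal(sum(lengths(cov) == 2), 2)   # the rest shared
  # a dedicated noiseless probe responds to its own isoform only
  sim0 <- simulate_dataset(sim_params(n_genes = 4, probes_per_gene = 4,
                                      n_samples = 15, n_train = 8,
                                      isoforms_per_gene = 2, noise_sd = 0,
                                      seed = 6))
  g0 <- rownames(sim0$expression)[2]
  ded <- sim0$map[[g0]][1]
  own <- sim0$transcript_map[[g0]][sim0$truth$coverage[[ded]]]
  expect_equal(cor(sim0$intensities[ded, ],
                   sim0$truth$latent_transcripts[own, ],
                   method = "spearman"), 1)
})

test_that("an all-shared probe design is flagged non-identifiable", {
  sim <- simulate_dataset(sim_params(n_genes = 4, probes_per_gene = 4,
                                     n_samples = 15, n_train = 8,
                                     isoforms_per_gene = 2,
                                     dedicated_probes = FALSE, seed = 7))
  expect_false(sim$truth$identifiable)
  expect_true(all(lengths(sim$truth$coverage) == 2))
})

test_that("planted group effects land on the declared genes", {
  sim <- simulate_dataset(sim_params(n_genes = 40, n_samples = 30,
                                     n_train = 20, de_frac = 0.1,
                                     de_lfc = log(8), seed = 8))
  expect_length(sim$truth$de_genes, 4)
  g <- sim$truth$groups
  lfc <- log(rowMeans(sim$truth$latent[, g == "B"]) /
               rowMeans(sim$truth$latent[, g == "A"]))
  de <- rownames(sim$truth$latent) %in% sim$truth$de_genes
  expect_gt(mean(abs(lfc[de])), mean(abs(lfc[!de])))
})

test_that("the default mixture design yields 33 annotated arrays", {
  pure <- cbind(heart = rexp(30, 0.02) + 1, brain = rexp(30, 0.02) + 1)
  rownames(pure) <- paste0("g", 1:30)
  mix <- simulate_mixture(pure, seed = 9)
  expect_equal(ncol(mix$intensities), 33)
  expect_equal(nrow(mix$metadata), 33)
  expect_equal(sort(unique(mix$metadata$proportion_A)),
               c(0, 0.05, 0.1, 0.25, 0.5, 0.75, 0.9, 0.95, 1))
  tab <- table(mix$metadata$proportion_A)
  expect_equal(unname(tab[["0.5"]]), 9)    # 3 biological x 3 technical
  expect_true(all(tab[names(tab) != "0.5"] == 3))
  expect_true(all(mix$metadata$tech_rep %in% 1:3))
})

test_that("pure endpoints and mixing linearity follow the construction", {
  pure <- cbind(heart = c(10, 0, 50), brain = c(2, 8, 0))
  rownames(pure) <- c("both", "brain_only", "heart_only")
  mix <- simulate_mixture(pure, bio_jitter_sd = 0, seed = 10)
  meta <- mix$metadata
  pure_heart <- meta$sample_id[meta$proportion_A == 1]
  for (s in pure_heart)
    expect_equal(unname(mix$latent[, s]), unname(pure[, "heart"]))
  # a gene expressed only in tissue A is linear in p with slope = pure value
  p <- meta$proportion_A
  expect_equal(unname(mix$latent["heart_only", ]), 50 * p)
  # technical replicates share the latent profile
  reps <- meta$sample_id[meta$proportion_A == 0.9]
  expect_equal(mix$latent[, reps[1]], mix$latent[, reps[2]])
})
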
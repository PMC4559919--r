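make_xy <- function(n = 30, p = 4, seed = 1, noise = 0.2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(paste0("s", seq_len(n)), paste0("p", seq_len(p))))
  list(X = X, y = 2 * X[, 1] + rnorm(n, sd = noise))
}

test_that("probe selection ranks by absolute correlation with stable ties", {
  set.seed(21)
  n <- 20
  y <- rnorm(n)
  X <- cbind(p1 = y, p2 = rnorm(n))
  expect_identical(select_probes(X, y, 1), 1L)
  # saturation: n beyond probe count returns everything in input order
  expect_identical(select_probes(X, y, 10), 1:2)
  expect_identical(select_probes(X, y, "all"), 1:2)
  expect_error(select_probes(X, y, 0), "n must be")
  # brute-force ranking oracle on 12 random probes
  X12 <- matrix(rnorm(n * 12), n, 12)
  sel <- select_probes(X12, y, 4)
  scores <- vapply(seq_len(12), function(j) abs(oracle_pearson(X12[, j], y)), 0)
  expect_identical(sel, order(scores, decreasing = TRUE)[1:4])
  # zero-variance probes score zero, not NA
  Xz <- cbind(p1 = rep(1, n), p2 = y)
  expect_identical(select_probes(Xz, y, 1), 2L)
})

test_that("a constant response yields stump trees predicting the constant", {
  d <- make_xy(20, 3, seed = 2)
  f <- qr_forest(d$X, rep(4.2, 20), ntree = 10, seed = 3)
  expect_true(all(vapply(f$trees, function(t) t$split_var[1] == -1L, TRUE)))
  expect_equal(unname(predict(f, d$X)), rep(4.2, 20))
})

test_that("fits are bit-reproducible from the seed and independent of R's RNG", {
  d <- make_xy(25, 3, seed = 4)
  set.seed(1); f1 <- qr_forest(d$X, d$y, ntree = 20, seed = 11)
  set.seed(999); f2 <- qr_forest(d$X, d$y, ntree = 20, seed = 11)
  expect_identical(serialize(f1, NULL), serialize(f2, NULL))
  f3 <- qr_forest(d$X, d$y, ntree = 20, seed = 12)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("trees match an independently coded reference grower draw for draw", {
  d <- make_xy(20, 3, seed = 5)
  ntree <- 5; mtry <- 2; min_node <- 3; seed <- 4242
  f <- qr_forest(d$X, d$y, ntree = ntree, mtry = mtry,
                 min_node_size = min_node, seed = seed)
  ys <- d$y / sd(d$y)
  rng <- minstd_new(seed)
  for (t in seq_len(ntree)) {
    ref <- oracle_grow_tree(d$X, ys, mtry, min_node, rng)
    got <- f$trees[[t]]
    expect_identical(got$split_var, ref$split_var)
    expect_equal(got$split_val, ref$split_val)
    expect_identical(got$left, ref$left)
    expect_identical(got$right, ref$right)
    expect_identical(got$leaf_samples, ref$leaf_samples)
    expect_identical(f$inbag[, t], ref$inbag)
  }
})

test_that("prediction semantics follow the stored leaves", {
  # hand-built forest: one stump tree whose leaf holds only sample 3
  y <- c(1, 2, 7, 4, 9)
  hand <- structure(list(
    trees = list(list(split_var = -1L, split_val = 0, left = -1L,
                      right = -1L, leaf_samples = list(3L))),
    inbag = matrix(c(0L, 0L, 1L, 0L, 0L), 5, 1),
    X = matrix(0, 5, 1), y = matrix(y, ncol = 1), n = 5,
    probe_ids = NULL, sample_ids = NULL, response_names = NULL,
    ntree = 1L, mtry = 1L, min_node_size = 5L, seed = 1),
    class = "qr_forest")
  # all quantiles collapse to the single leaf sample's response
  pr <- predict(hand, matrix(0, 1, 1), quantiles = c(0.05, 0.5, 0.95))
  expect_equal(unname(pr$quantiles), rep(7, 3), ignore_attr = TRUE)
  expect_equal(unname(pr$mean), 7)
  # single-tree forest: the mean is that tree's leaf mean
  d <- make_xy(15, 2, seed = 6)
  f1 <- qr_forest(d$X, d$y, ntree = 1, seed = 9)
  lv <- f1$trees[[1]]
  x0 <- d$X[4, , drop = FALSE]
  node <- 1L
  while (lv$split_var[node] != -1L) {
    node <- if (x0[lv$split_var[node]] <= lv$split_val[node]) lv$left[node]
            else lv$right[node]
  }
  expect_equal(unname(predict(f1, x0)), mean(d$y[lv$leaf_samples[[node]]]))
})

test_that("forest weights are a probability distribution matching brute force", {
  d <- make_xy(12, 3, seed = 7)
  f <- qr_forest(d$X, d$y, ntree = 3, min_node_size = 2, seed = 77)
  W <- qrf_weights(f, d$X)
  expect_true(all(W >= 0))
  expect_equal(unname(rowSums(W)), rep(1, 12), tolerance = 1e-10)
  for (i in c(1, 5, 12))
    expect_equal(unname(W[i, ]), oracle_weights(f, d$X[i, ]))
})

test_that("conditional quantiles are monotone and never extrapolate", {
  d <- make_xy(40, 3, seed = 8)
  f <- qr_forest(d$X, d$y, ntree = 50, seed = 5)
  qs <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  new <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, colnames(d$X)))
  pr <- predict(f, new, quantiles = qs)
  for (i in 1:10) {
    expect_false(is.unsorted(pr$quantiles[i, ]))
    expect_gte(pr$quantiles[i, 3], min(d$y))
    expect_lte(pr$quantiles[i, 3], max(d$y))
  }
  # quantiles agree with the brute-force weighted empirical distribution
  W <- qrf_weights(f, new)
  for (i in c(2, 9)) for (k in seq_along(qs))
    expect_equal(unname(pr$quantiles[i, k]),
                 unname(oracle_weighted_quantile(d$y, W[i, ], qs[k])))
})

test_that("a probe missing from newdata is a hard error naming it", {
  d <- make_xy(15, 3, seed = 9)
  f <- qr_forest(d$X, d$y, ntree = 5, seed = 2)
  bad <- d$X[, 1:2]
  expect_error(predict(f, bad), "p3")
})

test_that("OOB estimates use only trees excluding the sample", {
  # hand-chosen bootstraps over two stump trees
  y <- c(1, 2, 3, 4, 6)
  X <- matrix(0, 5, 1)
  tree_a <- list(split_var = -1L, split_val = 0, left = -1L, right = -1L,
                 leaf_samples = list(c(1L, 2L, 3L)))
  tree_b <- list(split_var = -1L, split_val = 0, left = -1L, right = -1L,
                 leaf_samples = list(c(2L, 3L, 4L, 5L)))
  inbag <- cbind(c(2L, 1L, 2L, 0L, 0L), c(0L, 1L, 1L, 2L, 1L))
  hand <- structure(list(trees = list(tree_a, tree_b), inbag = inbag,
                         X = X, y = matrix(y, ncol = 1), n = 5,
                         probe_ids = NULL, sample_ids = NULL,
                         response_names = NULL, ntree = 2L, mtry = 1L,
                         min_node_size = 5L, seed = 1),
                    class = "qr_forest")
  oob <- oob_predict(hand)
  # sample 1: OOB in tree b only -> mean(y[2:5]); samples 4,5: tree a only
  expect_equal(unname(oob),
               c(mean(y[2:5]), NA, NA, mean(y[1:3]), mean(y[1:3])))
})

test_that("every sample gets an OOB estimate once trees are plentiful", {
  d <- make_xy(30, 3, seed = 10)
  f <- qr_forest(d$X, d$y, ntree = 200, seed = 6)
  expect_false(anyNA(oob_predict(f)))
})

test_that("OOB correlation follows the Pearson formula with NA handling", {
  y <- rnorm(10)
  expect_equal(oob_correlation(y, y), 1)
  expect_equal(oob_correlation(-y + 3, y), -1)
  set.seed(30)
  a <- rnorm(10); b <- rnorm(10)
  expect_equal(oob_correlation(a, b), oracle_pearson(a, b))
  expect_true(is.na(oob_correlation(c(1, 2, NA, NA, NA, NA, NA, NA, NA, NA), y)))
  expect_true(is.na(oob_correlation(rep(1, 10), y)))
})

test_that("principal-component augmentation matches an eigendecomposition", {
  # k = 0 is a no-op
  set.seed(40)
  m <- matrix(rnorm(200), 10, 20,
              dimnames = list(paste0("p", 1:10), paste0("s", 1:20)))
  expect_null(seqpred:::fit_pca(m, 0))
  # rank-1 matrix: PC1 scores reproduce the column pattern up to sign/scale
  r1 <- outer(1:10, seq(0.5, 2, length.out = 20))
  dimnames(r1) <- dimnames(m)
  pc1 <- seqpred:::fit_pca(r1, 1)
  s1 <- seqpred:::pca_scores(pc1, r1)
  expect_equal(abs(cor(s1[, 1], seq(0.5, 2, length.out = 20))), 1)
  # random 20 x 10: scores match eigen of the covariance within 1e-8 up to sign
  X <- matrix(rnorm(200), 20, 10)   # samples x probes
  m2 <- t(X); dimnames(m2) <- list(paste0("p", 1:10), paste0("s", 1:20))
  pc <- seqpred:::fit_pca(m2, 3)
  sc <- seqpred:::pca_scores(pc, m2)
  ev <- eigen(cov(X))$vectors[, 1:3]
  want <- scale(X, center = TRUE, scale = FALSE) %*% ev
  for (k in 1:3) {
    sgn <- sign(sum(sc[, k] * want[, k]))
    expect_equal(unname(sc[, k]), sgn * unname(want[, k]), tolerance = 1e-8)
  }
})
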
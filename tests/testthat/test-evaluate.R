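rand_pair <- function(seed = 80, nf = 10, ns = 6) {
  set.seed(seed)
  truth <- matrix(rexp(nf * ns, 0.05), nf, ns,
                  dimnames = list(paste0("g", seq_len(nf)),
                                  paste0("s", seq_len(ns))))
  est <- truth * matrix(exp(rnorm(nf * ns, 0, 0.3)), nf, ns)
  list(est = est, truth = truth)
}

test_that("correlation reports are exact for identity and affine maps", {
  d <- rand_pair()
  rep1 <- correlation_report(d$truth, d$truth)
  expect_equal(rep1$per_sample$pearson, rep(1, 6))
  expect_equal(rep1$per_feature$spearman, rep(1, 10))
  expect_equal(rep1$summary$r_bar, 1)
  rep2 <- correlation_report(2 * d$truth + 7, d$truth)
  expect_equal(rep2$per_sample$pearson, rep(1, 6))
  expect_equal(rep2$summary$rho_bar, 1)
})

test_that("correlation entries equal direct formula recomputation", {
  d <- rand_pair(81)
  rep <- correlation_report(d$est, d$truth)
  for (s in c(1, 4)) {
    expect_equal(rep$per_sample$pearson[s],
                 oracle_pearson(d$est[, s], d$truth[, s]))
    expect_equal(rep$per_sample$spearman[s],
                 oracle_pearson(rank(d$est[, s]), rank(d$truth[, s])))
  }
  for (f in c(2, 9))
    expect_equal(rep$per_feature$pearson[f],
                 oracle_pearson(d$est[f, ], d$truth[f, ]))
})

test_that("constant vectors are excluded from correlation means, not zeroed", {
  d <- rand_pair(82)
  d$truth[3, ] <- 5
  rep <- correlation_report(d$est, d$truth)
  expect_true(is.na(rep$per_feature$pearson[3]))
  expect_equal(unname(rep$summary$cross_pearson["n_defined"]), 9)
  ok <- !is.na(rep$per_feature$pearson)
  expect_equal(rep$summary$r_bar, mean(rep$per_feature$pearson[ok]))
})

test_that("relative errors behave for exact, scaled and filtered data", {
  d <- rand_pair(83, nf = 30, ns = 10)
  z <- relative_error_summary(d$truth, d$truth)
  expect_equal(z$median_error, 0)
  expect_equal(z$median_abs_error, 0)
  s <- relative_error_summary(1.5 * d$truth, d$truth)
  expect_equal(s$median_error, 0.5)
  expect_true(all(abs(s$bins$mean_relerr - 0.5) < 1e-12))
})

test_that("the display window and cap match a brute-force filter", {
  set.seed(84)
  truth <- matrix(rexp(600, 0.02), 60, 10,
                  dimnames = list(paste0("g", 1:60), paste0("s", 1:10)))
  est <- truth * exp(rnorm(600, 0, 1))
  out <- relative_error_summary(est, truth, truth_min = 1, truth_max = 1000,
                                relerr_cap = 2, bin_size = 75)
  tv <- as.vector(truth); ev <- as.vector(est)
  win <- tv >= 1 & tv <= 1000
  rel <- (ev[win] - tv[win]) / tv[win]
  expect_equal(out$n_used, sum(win))
  expect_equal(out$n_capped, sum(rel >= 2))
  expect_equal(out$median_error, median(rel))
  expect_equal(nrow(out$bins), sum(rel < 2) %/% 75)
})

test_that("within-sample slopes equal the closed-form cov/var ratio", {
  d <- rand_pair(85)
  expect_equal(unname(within_sample_slope(d$truth, d$truth)$slopes),
               rep(1, 6))
  expect_equal(within_sample_slope(3 * d$truth, d$truth)$median_slope, 3)
  sl <- within_sample_slope(d$est, d$truth)
  s1 <- d$truth[, 1]; e1 <- d$est[, 1]
  expect_equal(unname(sl$slopes[1]),
               sum((s1 - mean(s1)) * (e1 - mean(e1))) / sum((s1 - mean(s1))^2))
})

test_that("differential-expression ranking is a deterministic permutation", {
  set.seed(86)
  m <- matrix(rnorm(50 * 12, 100, 10), 50, 12,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:12)))
  A <- paste0("s", 1:6); B <- paste0("s", 7:12)
  m["g7", B] <- m["g7", B] + 60          # strong planted shift
  m["g9", ] <- 100                       # degenerate flat feature
  d <- de_rank(m, A, B)
  expect_setequal(d$rank, 1:50)
  expect_equal(d$rank[d$feature_id == "g7"], 1L)
  expect_equal(d$p[d$feature_id == "g9"], 1)
  expect_equal(d$rank[d$feature_id == "g9"], 50L)
  # invariance to sample order within groups
  d2 <- de_rank(m, rev(A), sample(B))
  expect_identical(d$rank, d2$rank)
  # agreement with stats::t.test per feature
  tt <- t.test(m["g3", A], m["g3", B])
  expect_equal(d$t[d$feature_id == "g3"], unname(tt$statistic))
  expect_equal(d$p[d$feature_id == "g3"], tt$p.value)
})

test_that("a 5-sd planted shift ranks first in nearly all replicates", {
  hits <- 0L
  for (rep in 1:100) {
    set.seed(rep + 2000)
    m <- matrix(rnorm(30 * 20, 50, 2), 30, 20,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:20)))
    A <- paste0("s", 1:10); B <- paste0("s", 11:20)
    m["g5", B] <- m["g5", B] + 10       # 5 sd shift
    hits <- hits + (de_rank(m, A, B)$rank[5] == 1L)
  }
  expect_gte(hits, 99L)
})

test_that("BH adjustment reproduces the hand-computed example", {
  p <- c(0.01, 0.02, 0.03, 0.8)
  expect_equal(p.adjust(p, "BH"), c(0.04, 0.04, 0.04, 0.8))
  # q is monotone non-decreasing in p after step-up
  set.seed(87)
  pp <- runif(50)
  q <- p.adjust(pp, "BH")
  expect_false(is.unsorted(q[order(pp)]))
})

test_that("Lin's coefficient has its closed-form values and bound", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 6)
  expect_equal(lin_ccc(x, x), 1)
  # hand computation with population moments
  n <- 4
  cxy <- mean((x - mean(x)) * (y - mean(y)))
  want <- 2 * cxy / (mean((x - mean(x))^2) + mean((y - mean(y))^2) +
                       (mean(x) - mean(y))^2)
  expect_equal(lin_ccc(x, y), want)
  # a location shift is penalized even at perfect correlation
  expect_lt(lin_ccc(x, x + 2), 1)
  # |ccc| <= |r| across random draws; equality iff moments match
  set.seed(88)
  for (i in 1:25) {
    a <- rnorm(15); b <- rnorm(15, sd = runif(1, 0.5, 2))
    expect_lte(abs(lin_ccc(a, b)), abs(cor(a, b)) + 1e-12)
  }
  z <- rnorm(10)
  expect_equal(lin_ccc(z, z), cor(z, z))
  expect_true(is.na(lin_ccc(rep(1, 5), rep(1, 5))))
})

test_that("the cumulative Jaccard curve matches set arithmetic", {
  ids <- paste0("g", 1:10)
  expect_equal(cumulative_jaccard(ids, ids), rep(1, 10))
  Jrev <- cumulative_jaccard(ids, rev(ids))
  want <- c(rep(0, 5), (2 * (6:10) - 10) / 10)
  expect_equal(Jrev, want)
  # random permutations vs naive per-k set computation
  set.seed(89)
  u <- paste0("g", 1:50)
  a <- sample(u); b <- sample(u)
  J <- cumulative_jaccard(a, b)
  for (k in c(1, 7, 25, 50)) {
    inter <- length(intersect(a[1:k], b[1:k]))
    expect_equal(J[k], inter / length(union(a[1:k], b[1:k])))
    # J * |union| is an integer
    expect_equal(J[k] * (2 * k - inter), round(J[k] * (2 * k - inter)))
  }
  expect_equal(J[50], 1)
  expect_true(all(J >= 0))
  expect_error(cumulative_jaccard(a, a[1:49]), "permutations")
})
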
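# Independent reference implementations used as oracles.  These
# deliberately re-derive results with naive algorithms (explicit loops,
# all-pairs scans) so they share no code with the package internals.

# --- MINSTD stream replica (Park-Miller), matching the forest's private
# RNG draw by draw.  Plain double arithmetic throughout.
minstd_new <- function(seed) {
  m <- 2147483647
  s <- seed - floor(seed / m) * m
  if (s <= 0) s <- s + 2147483646
  env <- new.env()
  env$s <- s
  env
}
minstd_unif <- function(rng) {
  m <- 2147483647
  a <- 16807 * rng$s
  rng$s <- a - floor(a / m) * m
  rng$s / m
}
minstd_upto <- function(rng, k) {
  v <- floor(minstd_unif(rng) * k)
  if (v >= k) k - 1 else v
}

# --- reference grower for a single regression tree (univariate response),
# consuming the same RNG draws in the same order as the package's grower:
# n bootstrap draws, then per node (preorder, left child first) a partial
# Fisher-Yates of mtry predictors.  Splits maximize variance reduction with
# ties broken by lowest predictor then lowest threshold.  Accumulations use
# explicit double loops.
oracle_grow_tree <- function(X, ys, mtry, min_node, rng) {
  n <- nrow(X); p <- ncol(X)
  samp0 <- integer(n)
  for (i in seq_len(n)) samp0[i] <- as.integer(minstd_upto(rng, n))  # 0-based
  tree <- list(split_var = integer(0), split_val = numeric(0),
               left = integer(0), right = integer(0),
               leaf_samples = list())
  grow <- function(samp) {       # samp 0-based with multiplicity
    nn <- length(samp)
    best_var <- -1L; best_val <- 0; best_gain <- 0
    if (nn >= 2 * min_node) {
      tot <- 0
      for (i in seq_len(nn)) tot <- tot + ys[samp[i] + 1]
      base <- tot * tot / nn
      vars <- 0:(p - 1)
      m <- min(mtry, p)
      for (j in seq_len(m)) {
        k <- j + minstd_upto(rng, p - j + 1)
        tmp <- vars[j]; vars[j] <- vars[k]; vars[k] <- tmp
      }
      for (j in seq_len(m)) {
        v <- vars[j]
        xv <- X[samp + 1, v + 1]
        ord <- order(xv, seq_len(nn))      # stable: value then position
        cum <- 0
        for (i in seq_len(nn - 1)) {
          cum <- cum + ys[samp[ord[i]] + 1]
          xi <- xv[ord[i]]; xj <- xv[ord[i + 1]]
          if (xi == xj) next
          k <- i
          if (k < min_node || nn - k < min_node) next
          L <- cum; R <- tot - L
          g <- L * L / k + R * R / (nn - k)
          g <- g - base
          thr <- (xi + xj) / 2
          take <- FALSE
          if (g > best_gain) take <- TRUE
          else if (g == best_gain && best_var >= 0 &&
                   (v < best_var || (v == best_var && thr < best_val)))
            take <- TRUE
          if (take) { best_gain <- g; best_var <- v; best_val <- thr }
        }
      }
      if (best_gain <= 0) best_var <- -1L
    }
    me <- length(tree$split_var) + 1L
    tree$split_var[me] <<- -1L
    tree$split_val[me] <<- 0
    tree$left[me] <<- -1L
    tree$right[me] <<- -1L
    tree$leaf_samples[[me]] <<- integer(0)
    if (best_var < 0) {
      tree$leaf_samples[[me]] <<- as.integer(sort(unique(samp)) + 1L)
      return(me)
    }
    ls <- samp[X[samp + 1, best_var + 1] <= best_val]
    rs <- samp[X[samp + 1, best_var + 1] > best_val]
    tree$split_var[me] <<- best_var + 1L
    tree$split_val[me] <<- best_val
    tree$left[me] <<- grow(ls)
    tree$right[me] <<- grow(rs)
    me
  }
  grow(samp0)
  tree$inbag <- tabulate(samp0 + 1L, nbins = n)
  tree
}

# note: the package splits at k = i + 1 with i 0-based; here i is 1-based
# so the left-child count is k = i, matching the same partition.

# --- brute-force interval overlap (>= 1 shared base, same chrom)
oracle_overlaps <- function(features, probesets) {
  out <- NULL
  for (i in seq_len(nrow(probesets))) {
    for (j in seq_len(nrow(features))) {
      if (probesets$chrom[i] == features$chrom[j] &&
          probesets$start[i] < features$end[j] &&
          features$start[j] < probesets$end[i]) {
        out <- rbind(out, data.frame(probeset_id = probesets$id[i],
                                     feature_id = features$id[j],
                                     stringsAsFactors = FALSE))
      }
    }
  }
  if (is.null(out)) return(data.frame(probeset_id = character(0),
                                      feature_id = character(0)))
  out[order(out$probeset_id, out$feature_id), , drop = FALSE]
}

# --- brute-force Meinshausen weights from a forest's stored leaves
oracle_weights <- function(forest, xnew) {
  w <- numeric(forest$n)
  for (tree in forest$trees) {
    node <- 1L
    while (tree$split_var[node] != -1L) {
      v <- tree$split_var[node]
      node <- if (xnew[v] <= tree$split_val[node]) tree$left[node]
              else tree$right[node]
    }
    ls <- tree$leaf_samples[[node]]
    for (i in ls) w[i] <- w[i] + 1 / length(ls)
  }
  w / forest$ntree
}

oracle_weighted_quantile <- function(y, w, q) {
  ord <- order(y)
  cw <- 0
  for (i in ord) {
    cw <- cw + w[i]
    if (cw >= q - 1e-12) return(y[i])
  }
  y[ord[length(ord)]]
}

# --- textbook Pearson correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# small labelled interval table builder for mapping tests
itable <- function(id, chrom, start, end, strand = ".") {
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}
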
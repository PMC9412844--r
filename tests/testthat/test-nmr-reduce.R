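make_bucket_table <- function(v, prefix = "b") {
  dimnames(v) <- list(paste0("s", seq_len(nrow(v))),
                      paste0(prefix, seq_len(ncol(v))))
  feature_table(v, "metabolome_nmr")
}

test_that("L1 selection keeps a strong signal feature and drops noise", {
  hits <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    y <- rep(c(0, 1), each = n / 2)
    v <- cbind(y + rnorm(n, sd = 0.1),
               matrix(rnorm(n * 50), n, 50))
    tab <- make_bucket_table(v)
    sel <- select_informative_buckets(tab, factor(y), seed = seed)
    if ("b1" %in% sel$kept_feature_ids) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("selection keeps fewer features under permuted labels", {
  kept_true <- kept_perm <- numeric(20)
  for (seed in 1:20) {
    set.seed(seed)
    n <- 200
    y <- rep(c(0, 1), each = n / 2)
    v <- cbind(y + rnorm(n, sd = 0.2),
               2 * y + rnorm(n, sd = 0.4),
               -y + rnorm(n, sd = 0.3),
               matrix(rnorm(n * 48), n, 48))
    tab <- make_bucket_table(v)
    kept_true[seed] <- length(select_informative_buckets(
      tab, factor(y), seed = seed)$kept_feature_ids)
    kept_perm[seed] <- length(select_informative_buckets(
      tab, sample(factor(y)), seed = seed)$kept_feature_ids)
  }
  expect_lte(mean(kept_perm), mean(kept_true))
  expect_gte(mean(kept_true), 1)  # the planted signal is retained
})

test_that("constant features are never kept and tiny classes error", {
  set.seed(1)
  v <- cbind(rep(3, 40), matrix(rnorm(40 * 5), 40, 5))
  tab <- make_bucket_table(v)
  y <- rep(c("a", "b"), each = 20)
  sel <- select_informative_buckets(tab, y, seed = 1)
  expect_false("b1" %in% sel$kept_feature_ids)
  expect_true("b1" %in% sel$dropped)

  y_rare <- c(rep("a", 37), rep("b", 3))
  expect_error(select_informative_buckets(tab, y_rare, folds = 5),
               "fewer folds")
})

test_that("selection is invariant to feature order", {
  set.seed(21)
  n <- 100
  y <- rep(c("a", "b"), each = n / 2)
  v <- cbind((y == "a") * 1.5 + rnorm(n, sd = 0.4),
             matrix(rnorm(n * 12), n, 12))
  tab <- make_bucket_table(v)
  perm <- sample(ncol(v))
  tab_perm <- subset_table(tab, features = perm)
  s1 <- select_informative_buckets(tab, y, seed = 5)
  s2 <- select_informative_buckets(tab_perm, y, seed = 5)
  expect_setequal(s1$kept_feature_ids, s2$kept_feature_ids)
})

test_that("cophenetic threshold equals the exhaustive-cut oracle", {
  set.seed(30)
  for (rep in 1:100) {
    n_feat <- sample(5:20, 1)
    v <- matrix(rnorm(30 * n_feat), 30, n_feat)
    # inject some duplicated-with-noise columns so low merges exist
    v[, 1] <- v[, 2] + rnorm(30, sd = runif(1, 0.05, 0.5))
    d <- stats::as.dist(1 - cor(v))
    hc <- stats::hclust(d, method = "average")
    cap <- sample(c(0.7, 1.1, 2), 1)
    got <- suppressWarnings(select_cophenetic_threshold(hc, cap = cap))
    want <- oracle_min_nosingleton_cut(hc, cap = cap)
    expect_equal(got, want)
  }
})

test_that("cophenetic threshold handles the simple dendrogram shapes", {
  # two features merging at height 0.3
  v <- matrix(rnorm(40), 20, 2)
  v[, 2] <- v[, 1] + rnorm(20, sd = 0.1)
  r <- cor(v)[1, 2]
  hc <- stats::hclust(stats::as.dist(1 - cor(v)), method = "average")
  expect_equal(select_cophenetic_threshold(hc, cap = 1), 1 - r)

  # identical features all merge at height 0
  v2 <- matrix(rep(rnorm(10), 3), 10, 3)
  hc2 <- stats::hclust(stats::as.dist(1 - cor(v2)), method = "average")
  expect_equal(select_cophenetic_threshold(hc2), 0)
})

test_that("agglomeration recovers planted correlated blocks (ARI = 1)", {
  skip_if_not_installed("mclust")
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 60
    # heteroscedastic members: each block has one noisier resonance whose
    # late attachment resolves that block's last singleton
    blocks <- lapply(1:3, function(b) {
      core <- rnorm(n)
      sds <- c(0.05, 0.05, 0.05, 0.35)
      sapply(sds, function(s) core + rnorm(n, sd = s))
    })
    v <- do.call(cbind, blocks)
    tab <- make_bucket_table(v)
    map <- agglomerate_features(tab, cut = "auto", cap = 0.7)
    truth <- rep(1:3, each = 4)
    ari <- mclust::adjustedRandIndex(map$cluster_of, truth)
    if (isTRUE(all.equal(ari, 1))) ok <- ok + 1
  }
  expect_gte(ok, 19)
})

test_that("agglomeration distance is 1 - r with the documented edge cases", {
  set.seed(31)
  x <- rnorm(30)
  # identical features merge at height 0 -> one cluster at any cut
  tab <- make_bucket_table(cbind(x, x))
  map <- agglomerate_features(tab, cut = 0)
  expect_equal(length(unique(map$cluster_of)), 1)

  # near-independent features (d ~ 0.95) stay apart at cut 0.7
  y <- rnorm(30)
  r <- cor(x, y)
  skip_if(abs(r) > 0.3)  # extremely unlucky draw
  map2 <- agglomerate_features(make_bucket_table(cbind(x, y)), cut = 0.7)
  expect_equal(length(unique(map2$cluster_of)), 2)

  # zero-variance features are undefined under correlation distance
  expect_error(agglomerate_features(make_bucket_table(cbind(x, rep(1, 30)))),
               "zero-variance")
})

test_that("pooled agglomerates equal brute-force per-sample medians", {
  set.seed(32)
  for (rep in 1:10) {
    n_feat <- sample(4:12, 1)
    v <- matrix(rnorm(15 * n_feat), 15, n_feat)
    tab <- make_bucket_table(v)
    clusters <- sample(1:3, n_feat, replace = TRUE)
    names(clusters) <- feature_ids(tab)
    labs <- sort(unique(clusters))
    map <- structure(list(
      cluster_of = clusters, cut_height = 0.7,
      pooled_ids = stats::setNames(paste0("agg", seq_along(labs)),
                                   as.character(labs))),
      class = "agglomeration_map")
    pooled <- pool_agglomerates(tab, map)
    want <- oracle_pooled_medians(v, clusters)
    expect_equal(unname(pooled$values), unname(want))
  }
})

test_that("median pooling: singleton passes through, (1,2,9) pools to 2", {
  v <- matrix(c(1, 5, 2, 6, 9, 7, 4, 8), 2, 4,
              dimnames = list(c("s1", "s2"), paste0("b", 1:4)))
  tab <- feature_table(v, "metabolome_nmr")
  clusters <- stats::setNames(c(1L, 1L, 1L, 2L), paste0("b", 1:4))
  map <- structure(list(cluster_of = clusters, cut_height = 0.7,
                        pooled_ids = c("1" = "agg1", "2" = "agg2")),
                   class = "agglomeration_map")
  pooled <- pool_agglomerates(tab, map)
  expect_equal(unname(pooled$values[, "agg1"]), c(2, 6))  # median of (1,2,9)
  expect_equal(unname(pooled$values[, "agg2"]), unname(v[, "b4"]))
  expect_true(all(pooled$units == "pooled_intensity"))

  expect_error(pool_agglomerates(subset_table(tab, features = 1:4), structure(
    list(cluster_of = clusters[1:3], cut_height = 0.7,
         pooled_ids = c("1" = "agg1")), class = "agglomeration_map")),
    "missing from agglomeration map")
})

test_that("pooled features are mutually distant after agglomeration", {
  # intra-molecule correlation >= 0.95 collapses into pooled features whose
  # pairwise correlation stays below the cut's implied bound
  ok <- 0
  for (seed in 1:20) {
    set.seed(seed)
    n <- 80
    # four resonances tight around the molecule latent plus one at lower SNR
    # (still >= 0.95 correlated); its late attachment closes the block
    blocks <- lapply(1:4, function(b) {
      core <- rnorm(n)
      sapply(c(0.05, 0.05, 0.05, 0.05, 0.32),
             function(s) core + rnorm(n, sd = s))
    })
    tab <- make_bucket_table(do.call(cbind, blocks))
    map <- suppressWarnings(agglomerate_features(tab, cut = "auto", cap = 0.7))
    pooled <- pool_agglomerates(tab, map)
    r <- cor(pooled$values)
    max_off <- max(r[upper.tri(r)])
    # features kept apart by the cut sit at distance > cut_height,
    # i.e. correlate below 1 - cut_height
    if (max_off < 1 - map$cut_height) ok <- ok + 1
  }
  expect_gte(ok, 18)
})
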
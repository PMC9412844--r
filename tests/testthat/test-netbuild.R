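test_that("spearman matrix matches rank-then-Pearson and handles monotone maps", {
  set.seed(40)
  tab <- random_table(30, 10)
  got <- spearman_matrix(tab)
  want <- oracle_spearman(tab$values)
  expect_equal(unclass(got)[1:10, 1:10], want, tolerance = 1e-12,
               ignore_attr = TRUE)

  x <- c(-2, -1, 0, 1, 2)
  v <- cbind(x = x, cube = x^3, rev = rev(x))
  rownames(v) <- paste0("s", 1:5)
  rho <- spearman_matrix(feature_table(v, "microbiome"))
  expect_equal(rho["x", "cube"], 1)
  expect_equal(rho["x", "rev"], -1)
})

test_that("zero-variance features get zero correlations with a warning", {
  set.seed(41)
  v <- cbind(matrix(rnorm(20), 10, 2), rep(5, 10))
  dimnames(v) <- list(paste0("s", 1:10), c("f1", "f2", "zv"))
  tab <- feature_table(v, "microbiome")
  expect_warning(rho <- spearman_matrix(tab), "zero-variance")
  expect_true(all(rho["zv", c("f1", "f2")] == 0))
  expect_equal(rho["zv", "zv"], 1)
})

test_that("significance threshold matches the grid-scan oracle and decreases in n", {
  for (n in c(5, 10, 30, 90, 200)) {
    got <- min_significant_threshold(n, 0.05)
    want <- oracle_min_sig_threshold(n, 0.05)
    expect_lt(abs(got - want), 2e-6)  # grid resolution 1e-6 + root tolerance
  }
  rhos <- sapply(5:200, min_significant_threshold, alpha = 0.05)
  expect_true(all(diff(rhos) < 0))
  expect_error(min_significant_threshold(3), "n >= 4")
})

test_that("significance threshold brackets the alpha level", {
  pval <- function(rho, n) {
    t <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(abs(t), df = n - 2, lower.tail = FALSE)
  }
  for (n in c(6, 25, 120)) {
    r <- min_significant_threshold(n, 0.05)
    expect_lt(pval(r + 1e-4, n), 0.05)
    expect_gte(pval(r - 1e-4, n), 0.05)
  }
})

test_that("edges form strictly above the threshold in both modes", {
  rho <- matrix(0.8, 3, 3); diag(rho) <- 1
  dimnames(rho) <- list(paste0("f", 1:3), paste0("f", 1:3))
  net <- build_network(rho, 0.7)
  expect_equal(igraph::ecount(net$graph), 3)  # triangle

  expect_warning(net1 <- build_network(rho, 1), "empty edge set")
  expect_equal(igraph::ecount(net1$graph), 0)
  expect_equal(igraph::vcount(net1$graph), 3)  # isolated nodes retained

  # boundary: rho == t makes no edge
  net_eq <- build_network(rho, 0.8)
  expect_equal(igraph::ecount(net_eq$graph), 0)

  rho2 <- rho; rho2[1, 2] <- rho2[2, 1] <- -0.9
  expect_equal(igraph::ecount(build_network(rho2, 0.7, mode = "signed")$graph), 2)
  expect_equal(igraph::ecount(build_network(rho2, 0.7, mode = "absolute")$graph), 3)
})

test_that("edge counts match a brute-force double loop on random matrices", {
  set.seed(42)
  for (rep in 1:10) {
    tab <- random_table(20, 20)
    rho <- spearman_matrix(tab)
    t <- runif(1, 0.1, 0.6)
    net <- build_network(rho, t)
    cnt <- 0
    for (i in 1:19) for (j in (i + 1):20) if (rho[i, j] > t) cnt <- cnt + 1
    expect_equal(igraph::ecount(net$graph), cnt)
  }
})

test_that("edge sets are monotone in the threshold and Spearman-invariant", {
  set.seed(43)
  for (rep in 1:50) {
    tab <- random_table(25, 40)
    rho <- spearman_matrix(tab)
    e05 <- edge_keys(build_network(rho, 0.5))
    e07 <- edge_keys(build_network(rho, 0.7))
    expect_true(all(e07 %in% e05))

    # strictly increasing transforms leave the network identical
    transforms <- list(function(x) exp(x), function(x) x^3,
                       function(x) atan(x) * 2, function(x) 5 * x - 7)
    v2 <- tab$values
    for (j in seq_len(ncol(v2))) {
      f <- transforms[[sample.int(4, 1)]]
      v2[, j] <- f(v2[, j])
    }
    tab2 <- feature_table(v2, tab$feature_type)
    e2 <- edge_keys(build_network(spearman_matrix(tab2), 0.5))
    expect_identical(e05, e2)
  }
})

test_that("network is invariant to sample order", {
  set.seed(44)
  tab <- random_table(15, 8)
  e1 <- edge_keys(build_network(spearman_matrix(tab), 0.3))
  tab_shuf <- subset_table(tab, samples = sample(15))
  e2 <- edge_keys(build_network(spearman_matrix(tab_shuf), 0.3))
  expect_identical(e1, e2)
})

test_that("group policy builds 2 networks at T0 and 4 at Te with 0.5/0.7", {
  cfg <- sim_config(n_subjects_per_cell = 10, seed = 99)
  cohort <- simulate_cohort(cfg)
  tab <- feature_table(rbind(cohort$t0$values, cohort$te$values),
                       cohort$t0$feature_type, cohort$t0$units)
  nets <- apply_group_policy(tab, cohort$design)
  expect_setequal(names(nets),
                  c("T0_F", "T0_M", "Te_F_A", "Te_F_P", "Te_M_A", "Te_M_P"))
  for (g in names(nets)) {
    p <- nets[[g]]$provenance
    expect_equal(p$t, if (startsWith(g, "T0")) 0.5 else 0.7)
    expect_equal(p$mode, "signed")
    expect_equal(p$n_samples, if (startsWith(g, "T0")) 20L else 10L)
  }
})

test_that("significance policy records the resolved threshold", {
  cfg <- sim_config(n_subjects_per_cell = 8, seed = 7)
  cohort <- simulate_cohort(cfg)
  tab <- feature_table(rbind(cohort$t0$values, cohort$te$values),
                       cohort$t0$feature_type, cohort$t0$units)
  nets <- apply_group_policy(
    tab, cohort$design,
    policies = list(Te_F_A = significance_policy(0.05)))
  expect_equal(nets$Te_F_A$provenance$t, min_significant_threshold(8, 0.05))
  expect_equal(nets$Te_F_A$provenance$policy, "significance")
  expect_equal(nets$T0_F$provenance$t, 0.5)
})

test_that("degenerate designs: one arm warns, small groups error", {
  cfg <- sim_config(n_subjects_per_cell = 6, seed = 3)
  cohort <- simulate_cohort(cfg)
  d <- cohort$design
  keep <- d$arm == "A"
  tab <- feature_table(rbind(cohort$t0$values, cohort$te$values),
                       cohort$t0$feature_type, cohort$t0$units)
  tab_a <- subset_table(tab, samples = which(keep[match(sample_ids(tab),
                                                        d$sample_id)]))
  w <- capture_warnings(nets <- apply_group_policy(tab_a, d))
  expect_true(any(grepl("one arm", w)))
  expect_setequal(names(nets), c("T0_F", "T0_M", "Te_F_A", "Te_M_A"))

  tiny <- subset_table(tab, samples = 1:3)
  expect_error(suppressWarnings(apply_group_policy(tiny, d)), ">= 4")
})

test_that("soft-threshold power recovers a scale-free toy and is monotone", {
  # expected-degree (Chung-Lu) weights from an exact power-law degree
  # sequence: count(d) ~ d^-2.5, so connectivity at beta = 1 is scale-free
  set.seed(45)
  cnt <- round(200 * (1:15)^(-2.5))
  cnt <- cnt[cnt >= 1]
  target_k <- rep(seq_along(cnt), cnt)
  n <- length(target_k)
  w <- outer(target_k, target_k) / sum(target_k)
  diag(w) <- 0
  dimnames(w) <- list(paste0("f", 1:n), paste0("f", 1:n))
  res <- soft_threshold_power(w, powers = 1:5, rsq_target = 0.95)
  expect_gte(res$fit_table$rsq[1], 0.95)
  expect_equal(res$power, 1L)

  # k_i never increases with beta when |rho| <= 1
  rho <- spearman_matrix(random_table(20, 15))
  a <- abs(rho); diag(a) <- 0
  k2 <- rowSums(a^2); k4 <- rowSums(a^4)
  expect_true(all(k4 <= k2 + 1e-12))

  one <- soft_threshold_power(rho, powers = 6)
  expect_equal(one$power, 6L)
  zero <- matrix(0, 4, 4); diag(zero) <- 1
  expect_error(soft_threshold_power(zero), "zero")
})
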
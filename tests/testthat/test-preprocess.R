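make_ra_table <- function(values, ids = NULL) {
  if (is.null(ids)) ids <- paste0("f", seq_len(ncol(values)))
  dimnames(values) <- list(paste0("s", seq_len(nrow(values))), ids)
  feature_table(values, "microbiome", "percent_RA")
}

test_that("median filter removes features below the threshold", {
  v <- cbind(rep(0.3, 5), rep(0.6, 5), rep(50, 5))
  tab <- make_ra_table(v)
  kept <- filter_by_median_abundance(tab, filter_config(0.5, "pooled"))
  expect_identical(feature_ids(kept), c("f2", "f3"))
  expect_identical(attr(kept, "removed"), "f1")

  all_kept <- filter_by_median_abundance(tab, filter_config(0, "pooled"))
  expect_equal(ncol(all_kept$values), 3)
})

test_that("union scope keeps a feature passing at either timepoint", {
  # feature passes at T0 (median 0.6) but not Te (median 0.2)
  v <- matrix(c(0.6, 0.6, 0.6, 0.2, 0.2, 0.2), ncol = 1)
  tab <- make_ra_table(v)
  d <- sample_design(sample_ids(tab), paste0("p", c(1:3, 1:3)),
                     rep("F", 6), rep(c("T0", "Te"), each = 3), rep("A", 6))
  keep_union <- filter_by_median_abundance(
    tab, filter_config(0.5, "per_timepoint_union"), d)
  expect_identical(feature_ids(keep_union), "f1")
  expect_warning(
    keep_inter <- filter_by_median_abundance(
      tab, filter_config(0.5, "per_timepoint_intersection"), d),
    "removed every feature")
  expect_length(feature_ids(keep_inter), 0)
  expect_true(isTRUE(attr(keep_inter, "empty")))
})

test_that("median filter is idempotent", {
  set.seed(7)
  v <- matrix(rexp(60, rate = 1), 10, 6)
  tab <- make_ra_table(v)
  once <- filter_by_median_abundance(tab, filter_config(0.5, "pooled"))
  twice <- filter_by_median_abundance(once, filter_config(0.5, "pooled"))
  expect_identical(feature_ids(once), feature_ids(twice))
  expect_equal(once$values, twice$values)
})

test_that("log transform handles units, zeros and pseudocounts", {
  v <- matrix(c(1, 2, 4, 8), 2, 2, dimnames = list(c("s1", "s2"),
                                                   c("f1", "f2")))
  tab <- feature_table(v, "microbiome", "percent_RA")
  lt <- log_transform(tab, pseudocount = 0)
  expect_equal(lt$values[1, 1], 0)
  expect_equal(lt$values, log(v))
  expect_match(unname(lt$units[1]), "log_")

  v0 <- v; v0[1, 1] <- 0
  tab0 <- feature_table(v0, "microbiome")
  expect_error(log_transform(tab0, pseudocount = 0), "pseudocount")
  # automatic pseudocount: half the smallest positive value
  auto <- log_transform(tab0)
  expect_equal(attr(auto, "pseudocount"), 1)
  expect_error(log_transform(feature_table(-v, "microbiome")), "non-negative")
})

test_that("log transform reduces log-normal skewness to near zero", {
  set.seed(42)
  x <- exp(rnorm(10000, sd = 1))
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  tab <- feature_table(matrix(x, ncol = 1,
                              dimnames = list(paste0("s", 1:10000), "f1")),
                       "microbiome")
  lt <- log_transform(tab, pseudocount = 0)
  expect_lt(abs(skew(lt$values[, 1])), 0.2)
  expect_lt(abs(skew(lt$values[, 1])), skew(x))
})

test_that("PQN undoes an exact dilution and leaves identical samples alone", {
  set.seed(5)
  m <- rexp(40) + 0.1
  ppm <- seq(9, 0.5, length.out = 40)
  # samples 1-4 identical (they ARE the reference median), sample 5 = 2x
  diluted <- rbind(m, m, m, m, 2 * m)
  out <- pqn_normalize(spectra_matrix(diluted, ppm))
  expect_equal(unname(attr(out, "factors")[5, 1]), 2)
  expect_equal(unname(out$values[5, ]), unname(m))

  same <- matrix(rep(m, each = 4), 4, 40)
  out2 <- pqn_normalize(spectra_matrix(same, ppm))
  expect_equal(out2$values, same, ignore_attr = TRUE)
})

test_that("regional PQN is invariant to per-sample per-region rescaling", {
  set.seed(6)
  v <- matrix(rexp(6 * 90) + 0.05, 6, 90)
  ppm <- seq(10, 0.1, length.out = 90)
  regions <- region_spec(list(aromatic = c(6.5, 10.5), hydroxylic = c(4.5, 6.5),
                              aliphatic = c(0, 4.5)))
  ref <- pqn_normalize(spectra_matrix(v, ppm), regions)
  scaled <- v
  for (r in 1:3) {
    lo <- regions$bounds[r, "lo"]; hi <- regions$bounds[r, "hi"]
    cols <- which(ppm >= lo & ppm < hi)
    for (s in 1:6) scaled[s, cols] <- scaled[s, cols] * runif(1, 0.2, 5)
  }
  out <- pqn_normalize(spectra_matrix(scaled, ppm), regions)
  # invariance holds up to the batch normalisation constant of each region
  # (the median region area), which cancels in rank correlations downstream
  for (r in 1:3) {
    lo <- regions$bounds[r, "lo"]; hi <- regions$bounds[r, "hi"]
    cols <- which(ppm >= lo & ppm < hi)
    g <- median(rowSums(scaled[, cols])) / median(rowSums(v[, cols]))
    expect_equal(out$values[, cols] / g, ref$values[, cols],
                 tolerance = 1e-10)
  }
})

test_that("PQN errors on an all-zero sample region", {
  v <- matrix(1, 3, 10); v[2, 1:5] <- 0
  ppm <- seq(1, 10, length.out = 10)
  regions <- region_spec(list(low = c(0, 5.5), high = c(5.5, 11)))
  expect_error(pqn_normalize(spectra_matrix(v, ppm), regions),
               "all-zero region")
})

test_that("binning pools window means with the half-window trailing rule", {
  set.seed(8)
  # 1050 points at width 150 -> 7 bins, each the window mean
  v <- matrix(rexp(2 * 1050), 2, 1050)
  sp <- spectra_matrix(v, ppm = seq(10, 0.001, length.out = 1050))
  binned <- bin_spectrum(sp, width = 150)
  expect_equal(ncol(binned$values), 7)
  for (b in 1:7) {
    cols <- ((b - 1) * 150 + 1):(b * 150)
    expect_equal(unname(binned$values[, b]), unname(rowMeans(v[, cols])))
  }
  expect_true(all(binned$feature_type == "metabolome_nmr"))

  # constant spectrum stays constant
  cv <- matrix(7, 2, 300)
  cb <- bin_spectrum(spectra_matrix(cv, seq_len(300)), 150)
  expect_true(all(cb$values == 7))

  # trailing window: 40 extra points (< width/2) dropped, 100 (>= 75) kept
  short <- spectra_matrix(matrix(1, 2, 340), seq_len(340))
  expect_equal(ncol(bin_spectrum(short, 150)$values), 2)
  expect_equal(attr(bin_spectrum(short, 150), "dropped_points"), 40L)
  long <- spectra_matrix(matrix(1, 2, 400), seq_len(400))
  expect_equal(ncol(bin_spectrum(long, 150)$values), 3)
  expect_error(bin_spectrum(short, 1000), "exceeds")
})

test_that("binning at width 1 is the identity on values", {
  set.seed(9)
  v <- matrix(rexp(3 * 25), 3, 25)
  sp <- spectra_matrix(v, seq(5, 1, length.out = 25))
  binned <- bin_spectrum(sp, width = 1)
  expect_equal(unname(binned$values), unname(v))
})
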
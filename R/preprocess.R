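# Per-omics preprocessing: median relative-abundance filtering, log
# transforms, regional PQN normalisation of spectra and fixed-width binning.

#' Construct a spectra matrix
#'
#' Pre-binning 1H NMR profiles: samples in rows, spectral points in columns,
#' with a strictly monotone chemical-shift axis in ppm.
#'
#' @param values Non-negative numeric matrix (samples x points) with sample
#'   ids as rownames.
#' @param ppm Numeric axis, one chemical-shift position per column, strictly
#'   monotone (NMR convention is decreasing ppm, but either direction works).
#' @return An object of class `spectra_matrix`.
#' @export
spectra_matrix <- function(values, ppm) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (length(ppm) != ncol(values)) {
    stop("`ppm` must have one entry per spectral point", call. = FALSE)
  }
  d <- diff(ppm)
  if (length(d) > 0 && !(all(d > 0) || all(d < 0))) {
    stop("`ppm` axis must be strictly monotone", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("spectral intensities must be non-negative", call. = FALSE)
  }
  if (is.null(rownames(values))) {
    rownames(values) <- paste0("S", seq_len(nrow(values)))
  }
  structure(list(values = values, ppm = as.numeric(ppm)),
            class = "spectra_matrix")
}

#' @export
print.spectra_matrix <- function(x, ...) {
  cat(sprintf("<spectra_matrix> %d samples x %d points, ppm %.3f..%.3f\n",
              nrow(x$values), ncol(x$values), x$ppm[1],
              x$ppm[length(x$ppm)]))
  invisible(x)
}

#' Define spectral regions for regional normalisation
#'
#' Half-open ppm intervals `[lo, hi)`, typically the aromatic, hydroxylic and
#' aliphatic regions of a 1H NMR spectrum. Intervals must not overlap. Region
#' bounds are configuration, not constants: sensible limits depend on the
#' solvent, field strength and excised regions of the particular study.
#'
#' @param regions A list of length-2 numeric vectors `c(lo, hi)` or a 2-column
#'   matrix; optionally named.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(regions) {
  if (is.matrix(regions)) {
    regions <- lapply(seq_len(nrow(regions)), function(i) regions[i, ])
  }
  stopifnot(is.list(regions), length(regions) >= 1)
  m <- t(vapply(regions, function(r) {
    stopifnot(length(r) == 2)
    sort(as.numeric(r))
  }, numeric(2)))
  colnames(m) <- c("lo", "hi")
  if (is.null(names(regions))) {
    rownames(m) <- paste0("region", seq_len(nrow(m)))
  } else {
    rownames(m) <- names(regions)
  }
  o <- order(m[, "lo"])
  if (any(m[o, "hi"][-nrow(m)] > m[o, "lo"][-1] + 1e-12)) {
    stop("regions overlap", call. = FALSE)
  }
  structure(list(bounds = m), class = "region_spec")
}

region_indices <- function(spectra, spec) {
  lapply(seq_len(nrow(spec$bounds)), function(i) {
    lo <- spec$bounds[i, "lo"]
    hi <- spec$bounds[i, "hi"]
    which(spectra$ppm >= lo & spectra$ppm < hi)
  })
}

#' Filtering configuration for relative-abundance features
#'
#' @param ra_threshold Median relative-abundance threshold in percent
#'   (default 0.5): features with a median below it are removed.
#' @param scope How medians at the two timepoints combine:
#'   `"per_timepoint_union"` keeps a feature passing at T0 *or* Te (the
#'   default, so baseline and endpoint networks share a node set),
#'   `"per_timepoint_intersection"` requires both, `"pooled"` uses one median
#'   over all samples.
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(ra_threshold = 0.5,
                          scope = c("per_timepoint_union",
                                    "per_timepoint_intersection", "pooled")) {
  scope <- match.arg(scope)
  stopifnot(is.numeric(ra_threshold), length(ra_threshold) == 1,
            ra_threshold >= 0)
  structure(list(ra_threshold = ra_threshold, scope = scope),
            class = "filter_config")
}

#' Median relative-abundance filter
#'
#' Removes features whose median relative abundance falls below the threshold,
#' the guard against sparse taxa and trace volatiles whose skewed distributions
#' would otherwise create spurious correlations. Medians with even sample
#' counts are the mean of the two central order statistics.
#'
#' @param table A `feature_table` of relative abundances in percent.
#' @param cfg A [filter_config()].
#' @param design A [sample_design()]; required for per-timepoint scopes.
#' @return The filtered `feature_table`. Removed feature ids are recorded in
#'   attribute `removed`; if nothing survives, a warning is raised and
#'   attribute `empty` is set (downstream network construction refuses empty
#'   tables).
#' @export
filter_by_median_abundance <- function(table, cfg = filter_config(),
                                       design = NULL) {
  validate_feature_table(table)
  stopifnot(inherits(cfg, "filter_config"))
  v <- table$values
  if (cfg$scope == "pooled") {
    keep <- apply(v, 2, stats::median) >= cfg$ra_threshold
  } else {
    if (is.null(design)) {
      stop("per-timepoint scopes need `design` to identify T0/Te samples",
           call. = FALSE)
    }
    d <- design_for(table, design)
    med_by_tp <- vapply(c("T0", "Te"), function(tp) {
      rows <- d$timepoint == tp
      if (!any(rows)) return(rep(NA_real_, ncol(v)))
      apply(v[rows, , drop = FALSE], 2, stats::median)
    }, numeric(ncol(v)))
    if (!is.matrix(med_by_tp)) med_by_tp <- matrix(med_by_tp, nrow = 1)
    pass <- med_by_tp >= cfg$ra_threshold
    keep <- if (cfg$scope == "per_timepoint_union") {
      apply(pass, 1, any, na.rm = TRUE)
    } else {
      apply(pass, 1, all, na.rm = TRUE)
    }
  }
  removed <- feature_ids(table)[!keep]
  if (!any(keep)) {
    warning("median-abundance filter removed every feature", call. = FALSE)
    out <- subset_table(table, features = which(keep))
    attr(out, "removed") <- removed
    attr(out, "empty") <- TRUE
    return(out)
  }
  out <- subset_table(table, features = which(keep))
  attr(out, "removed") <- removed
  out
}

#' Natural-log transform
#'
#' Relative abundances passing the median filter are still right-skewed,
#' approximately log-normal; the log transform brings them near normality.
#' The base is irrelevant downstream (Spearman is rank-based); natural log is
#' used.
#'
#' @param table A `feature_table` with non-negative values.
#' @param pseudocount Added before taking logs. `NULL` (default) uses 0 when
#'   the table has no zeros, otherwise half the smallest positive value in the
#'   table.
#' @return A `feature_table` of `ln(value + pseudocount)` with updated unit
#'   tags; the pseudocount used is in attribute `pseudocount`.
#' @export
log_transform <- function(table, pseudocount = NULL) {
  validate_feature_table(table)
  v <- table$values
  if (any(v < 0, na.rm = TRUE)) {
    stop("log transform requires non-negative values", call. = FALSE)
  }
  if (is.null(pseudocount)) {
    pseudocount <- if (any(v == 0, na.rm = TRUE)) {
      min(v[v > 0], na.rm = TRUE) / 2
    } else {
      0
    }
  }
  stopifnot(is.numeric(pseudocount), length(pseudocount) == 1, pseudocount >= 0)
  if (pseudocount == 0 && any(v == 0, na.rm = TRUE)) {
    stop("zero values present; use a positive pseudocount", call. = FALSE)
  }
  out <- feature_table(log(v + pseudocount), table$feature_type,
                       paste0("log_", table$units))
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Probabilistic quotient normalisation by spectral region
#'
#' Corrects per-sample dilution under the assumption that most intensities
#' change by a common factor, using the canonical two-step algorithm per
#' region: (1) integral normalisation — every sample's region is scaled to
#' the median region area of the batch; (2) quotient correction — the
#' reference is the point-wise median of the area-normalised spectra, and
#' each sample is divided by the median quotient between its intensities and
#' the reference over the region's points (reference points equal to zero
#' are skipped). Regions are scaled independently (regional scaling), which
#' suits faecal extracts where the aromatic, hydroxylic and aliphatic
#' regions dilute differently. Because of the integral pre-step the result
#' is invariant to any per-sample, per-region rescaling, up to a single
#' batch-level constant per region (the median area), which cancels in the
#' rank correlations computed downstream.
#'
#' @param spectra A [spectra_matrix()] with at least two samples.
#' @param regions A [region_spec()]; `NULL` treats the whole axis as one
#'   region.
#' @return The normalised `spectra_matrix`; the total per-sample, per-region
#'   division factors are in attribute `factors` (an exact c-fold dilution of
#'   a sample shows up as a c-fold factor).
#' @export
pqn_normalize <- function(spectra, regions = NULL) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  v <- spectra$values
  if (nrow(v) < 2) stop("PQN needs at least 2 samples", call. = FALSE)
  if (is.null(regions)) {
    regions <- region_spec(list(full = c(min(spectra$ppm) - 1e-9,
                                         max(spectra$ppm) + 1e-9)))
  }
  idx <- region_indices(spectra, regions)
  factors <- matrix(NA_real_, nrow(v), length(idx),
                    dimnames = list(rownames(v), rownames(regions$bounds)))
  for (r in seq_along(idx)) {
    cols <- idx[[r]]
    if (length(cols) == 0) next
    block <- v[, cols, drop = FALSE]
    areas <- rowSums(block)
    zero <- which(areas == 0)
    if (length(zero) > 0) {
      stop(sprintf("sample \"%s\" has an all-zero region \"%s\"",
                   rownames(v)[zero[1]], rownames(regions$bounds)[r]),
           call. = FALSE)
    }
    target <- stats::median(areas)
    y <- block * (target / areas)
    ref <- apply(y, 2, stats::median)
    usable <- ref > 0
    if (!any(usable)) {
      stop(sprintf("region \"%s\": reference spectrum is all zero",
                   rownames(regions$bounds)[r]), call. = FALSE)
    }
    for (s in seq_len(nrow(v))) {
      q <- stats::median(y[s, usable] / ref[usable])
      factors[s, r] <- q * areas[s] / target
      v[s, cols] <- y[s, ] / q
    }
  }
  out <- spectra_matrix(v, spectra$ppm)
  attr(out, "factors") <- factors
  out
}

#' Bin a spectrum into fixed-width intervals
#'
#' Pools consecutive non-overlapping windows of `width` points by their mean,
#' turning the spectral profile into bucket features (e.g. 60,000 points at
#' width 150 give 400 buckets). A trailing partial window is pooled if it
#' holds at least `width / 2` points, otherwise dropped (logged in attribute
#' `dropped_points`). Bucket ids carry the ppm interval.
#'
#' @param spectra A [spectra_matrix()].
#' @param width Window width in data points (>= 1).
#' @return A `feature_table` with `feature_type = "metabolome_nmr"`.
#' @export
bin_spectrum <- function(spectra, width = 150) {
  stopifnot(inherits(spectra, "spectra_matrix"))
  width <- as.integer(width)
  np <- ncol(spectra$values)
  if (width < 1) stop("`width` must be >= 1", call. = FALSE)
  if (width > np) {
    stop(sprintf("`width` (%d) exceeds the number of spectral points (%d)",
                 width, np), call. = FALSE)
  }
  n_full <- np %/% width
  rest <- np %% width
  keep_partial <- rest >= width / 2
  n_bins <- n_full + as.integer(keep_partial)
  starts <- (seq_len(n_bins) - 1L) * width + 1L
  ends <- pmin(starts + width - 1L, np)
  vals <- vapply(seq_len(n_bins), function(b) {
    rowMeans(spectra$values[, starts[b]:ends[b], drop = FALSE])
  }, numeric(nrow(spectra$values)))
  if (nrow(spectra$values) == 1) vals <- matrix(vals, nrow = 1)
  ppm_lo <- pmin(spectra$ppm[starts], spectra$ppm[ends])
  ppm_hi <- pmax(spectra$ppm[starts], spectra$ppm[ends])
  ids <- sprintf("nmr_%0*d_ppm_%.4f_%.4f", nchar(n_bins), seq_len(n_bins),
                 ppm_lo, ppm_hi)
  dimnames(vals) <- list(rownames(spectra$values), ids)
  out <- feature_table(vals, "metabolome_nmr", "intensity")
  attr(out, "dropped_points") <- if (keep_partial) 0L else rest
  attr(out, "bin_width") <- width
  out
}
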
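# Two-step NMR feature reduction. Step 1 deletes buckets uninformative for
# the study outcomes with a self-optimising L1-penalised multinomial logistic
# regression. Step 2 agglomerates the surviving buckets by correlation-based
# hierarchical clustering with cophenetic pruning and pools each agglomerate
# with the per-sample median. Without this reduction, intramolecular
# resonances form a densely connected giant component of spectral features
# that drowns the rest of the network's topology.

#' Select informative spectral buckets by L1 multinomial logistic regression
#'
#' Fits one multinomial objective (not one-vs-rest) with an L1 penalty over a
#' log-spaced grid of penalty strengths; the strength is self-optimised by
#' stratified cross-validated mean accuracy under the one-standard-error
#' rule: among penalties whose mean accuracy is within one standard error of
#' the best, the strongest (sparsest) is chosen. In addition, unless the best
#' accuracy beats the no-information rate (majority-class frequency) by at
#' least three standard errors, the fully penalised null model is selected.
#' Statistical ties therefore resolve toward sparsity, and uninformative
#' data (e.g. permuted labels) collapse to the null model instead of chasing
#' CV noise. Features are
#' z-scored internally before fitting; zero-variance features are
#' pre-dropped. A bucket is kept when its coefficient exceeds `tol` in
#' absolute value for at least one class.
#'
#' @param binned A `feature_table` of binned buckets.
#' @param labels Class label per sample (factor or character), e.g. the
#'   intervention arm or its interaction with timepoint.
#' @param folds Number of stratified CV folds (default 5).
#' @param lambda_grid Penalty strengths to scan; default 10 log-spaced points
#'   in `[1e-3, 1e3]`.
#' @param tol Coefficient zero-tolerance (default 1e-8).
#' @param seed Integer seed for fold assignment.
#' @return A `selection_result` list: `kept_feature_ids`,
#'   `coefficient_summary` (max |coef| over classes per kept feature),
#'   `optimizer_trace` (grid, CV accuracies, chosen strength) and `dropped`.
#' @export
select_informative_buckets <- function(binned, labels, folds = 5,
                                       lambda_grid = NULL, tol = 1e-8,
                                       seed = 1) {
  validate_feature_table(binned)
  labels <- as.factor(labels)
  if (length(labels) != nrow(binned$values)) {
    stop("`labels` must have one entry per sample", call. = FALSE)
  }
  if (nlevels(droplevels(labels)) < 2) {
    stop("need at least 2 classes", call. = FALSE)
  }
  labels <- droplevels(labels)
  cls_n <- table(labels)
  if (any(cls_n < folds)) {
    small <- names(cls_n)[cls_n < folds]
    stop(sprintf(
      "class(es) %s have fewer samples than folds (%d); use fewer folds",
      paste(small, collapse = ", "), folds), call. = FALSE)
  }
  if (is.null(lambda_grid)) {
    lambda_grid <- 10^seq(-3, 3, length.out = 10)
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)

  v <- binned$values
  sds <- apply(v, 2, stats::sd)
  dropped_const <- colnames(v)[sds == 0 | !is.finite(sds)]
  v <- v[, sds > 0 & is.finite(sds), drop = FALSE]
  if (ncol(v) < 1) stop("no non-constant features to select from", call. = FALSE)
  x <- scale(v)

  # stratified fold assignment, reproducible by seed
  fold_id <- integer(nrow(x))
  rs <- local_rng(seed)
  for (cl in levels(labels)) {
    rows <- which(labels == cl)
    fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
  }
  restore_rng(rs)

  acc <- matrix(NA_real_, folds, length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    fit <- glmnet::glmnet(x[tr, , drop = FALSE], labels[tr],
                          family = "multinomial", alpha = 1,
                          lambda = lambda_grid, standardize = FALSE)
    pred <- predict(fit, x[!tr, , drop = FALSE], s = lambda_grid,
                    type = "class")
    acc[f, ] <- colMeans(pred == as.character(labels[!tr]))
  }
  mean_acc <- colMeans(acc)
  se_acc <- apply(acc, 2, stats::sd) / sqrt(folds)
  best <- which.max(mean_acc)
  baseline <- max(table(labels)) / length(labels)  # no-information rate
  if (mean_acc[best] < baseline + 3 * se_acc[best]) {
    # nothing beats the majority-class rule convincingly: labels carry no
    # usable signal, fall back to the null (fully penalised) model
    lambda_star <- lambda_grid[1]
  } else {
    # one-standard-error rule; the grid is sorted decreasing, so the first
    # qualifying index is the strongest penalty
    lambda_star <- lambda_grid[which(mean_acc >= mean_acc[best] - se_acc[best])[1]]
  }

  full <- glmnet::glmnet(x, labels, family = "multinomial", alpha = 1,
                         lambda = lambda_grid, standardize = FALSE)
  co <- predict(full, s = lambda_star, type = "coefficients")
  max_abs <- Reduce(pmax, lapply(co, function(m) abs(as.numeric(m[-1, 1]))))
  names(max_abs) <- colnames(x)
  kept <- names(max_abs)[max_abs > tol]

  structure(list(
    kept_feature_ids = kept,
    coefficient_summary = max_abs[kept],
    optimizer_trace = list(lambda_grid = lambda_grid,
                           cv_accuracy = mean_acc,
                           chosen_lambda = lambda_star,
                           folds = folds, seed = seed),
    dropped = c(dropped_const, setdiff(colnames(x), kept))
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %d buckets kept (lambda = %.4g)\n",
              length(x$kept_feature_ids), x$optimizer_trace$chosen_lambda))
  invisible(x)
}

#' Minimum no-singleton cophenetic cut height
#'
#' Scans the dendrogram's merge heights from the bottom and returns the
#' smallest height at which cutting leaves no singleton cluster. If no such
#' height exists at or below `cap`, returns `cap` with a warning (some
#' buckets then stay singletons by necessity).
#'
#' @param hc An [stats::hclust] object over at least 2 leaves.
#' @param cap Upper bound on the returned height (default 0.7, i.e. a minimum
#'   intra-cluster Pearson correlation of 0.3 under the `1 - r` distance).
#' @return The cut height.
#' @export
select_cophenetic_threshold <- function(hc, cap = 0.7) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  if (n < 2) stop("dendrogram must have at least 2 leaves", call. = FALSE)
  heights <- sort(unique(hc$height))
  for (h in heights) {
    if (h > cap + 1e-12) break
    cl <- stats::cutree(hc, h = h)
    if (min(table(cl)) >= 2) return(h)
  }
  warning(sprintf(
    "no singleton-free cut at or below cap %.3g; returning the cap", cap),
    call. = FALSE)
  cap
}

#' Agglomerate correlated spectral buckets
#'
#' Groups highly correlated buckets — adjacent buckets of one signal and
#' resonances of the same or interdependent molecules — so each molecule-level
#' signal enters the network once. Distance is `1 - Pearson r` (signed, not
#' `1 - |r|`: anti-correlated buckets are not the same molecule);
#' average-linkage clustering is cut so the intra-cluster cophenetic distance
#' does not exceed the cut height.
#'
#' @param selected A `feature_table` of selected buckets (>= 2 features, no
#'   zero variance).
#' @param cut Numeric cut height, or `"auto"` (default) for the minimum
#'   no-singleton height via [select_cophenetic_threshold()], clipped to
#'   `cap`.
#' @param cap Maximal cophenetic distance allowed within a cluster
#'   (default 0.7).
#' @return An `agglomeration_map` list: `cluster_of` (bucket id -> cluster
#'   label), `cut_height`, `pooled_ids` (cluster label -> pooled feature id)
#'   and the `hclust` object.
#' @export
agglomerate_features <- function(selected, cut = "auto", cap = 0.7) {
  validate_feature_table(selected)
  v <- selected$values
  if (ncol(v) < 2) stop("agglomeration needs at least 2 features", call. = FALSE)
  sds <- apply(v, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    stop("zero-variance feature(s): ",
         paste(colnames(v)[sds == 0 | !is.finite(sds)], collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(v, method = "pearson")
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "average")
  cut_height <- if (identical(cut, "auto")) {
    min(select_cophenetic_threshold(hc, cap = cap), cap)
  } else {
    stopifnot(is.numeric(cut), length(cut) == 1, cut >= 0)
    cut
  }
  cl <- stats::cutree(hc, h = cut_height)
  labels <- sort(unique(cl))
  pooled_ids <- sprintf("nmr_agg_%0*d", nchar(length(labels)),
                        seq_along(labels))
  names(pooled_ids) <- as.character(labels)
  structure(list(cluster_of = cl, cut_height = cut_height,
                 pooled_ids = pooled_ids, hclust = hc),
            class = "agglomeration_map")
}

#' @export
print.agglomeration_map <- function(x, ...) {
  cat(sprintf("<agglomeration_map> %d buckets -> %d clusters (cut %.3f)\n",
              length(x$cluster_of), length(x$pooled_ids), x$cut_height))
  invisible(x)
}

#' Pool agglomerated buckets by the per-sample median
#'
#' @param selected The `feature_table` the map was built on.
#' @param map An [agglomerate_features()] result covering all of `selected`'s
#'   features.
#' @return A `feature_table` with one pooled feature per cluster
#'   (`feature_type = "metabolome_nmr"`, units `"pooled_intensity"`); the
#'   member buckets of each pooled feature are in attribute `members`.
#' @export
pool_agglomerates <- function(selected, map) {
  validate_feature_table(selected)
  stopifnot(inherits(map, "agglomeration_map"))
  miss <- setdiff(feature_ids(selected), names(map$cluster_of))
  if (length(miss) > 0) {
    stop("feature(s) missing from agglomeration map: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  cl <- map$cluster_of[feature_ids(selected)]
  labels <- sort(unique(cl))
  vals <- vapply(labels, function(lb) {
    cols <- names(cl)[cl == lb]
    apply(selected$values[, cols, drop = FALSE], 1, stats::median)
  }, numeric(nrow(selected$values)))
  if (nrow(selected$values) == 1) vals <- matrix(vals, nrow = 1)
  ids <- unname(map$pooled_ids[as.character(labels)])
  dimnames(vals) <- list(sample_ids(selected), ids)
  out <- feature_table(vals, "metabolome_nmr", "pooled_intensity")
  members <- lapply(labels, function(lb) names(cl)[cl == lb])
  names(members) <- ids
  attr(out, "members") <- members
  out
}

#' Full two-step NMR reduction
#'
#' Convenience wrapper: select informative buckets, then agglomerate and pool
#' them. Degenerate outcomes are handled gracefully: if no bucket survives
#' selection an empty table is returned with a warning; a single surviving
#' bucket is passed through unpooled.
#'
#' @inheritParams select_informative_buckets
#' @inheritParams agglomerate_features
#' @return A list with `table` (pooled `feature_table`), `selection` and
#'   `map` (`NULL` when agglomeration was skipped).
#' @export
reduce_nmr <- function(binned, labels, folds = 5, lambda_grid = NULL,
                       cut = "auto", cap = 0.7, seed = 1) {
  sel <- select_informative_buckets(binned, labels, folds = folds,
                                    lambda_grid = lambda_grid, seed = seed)
  kept <- sel$kept_feature_ids
  if (length(kept) == 0) {
    warning("no informative buckets selected; NMR block is empty",
            call. = FALSE)
    empty <- binned$values[, 0, drop = FALSE]
    return(list(table = feature_table(
      empty, character(0), character(0)), selection = sel, map = NULL))
  }
  selected <- subset_table(binned, features = kept)
  if (length(kept) == 1) {
    out <- selected
    out$units[] <- "pooled_intensity"
    return(list(table = out, selection = sel, map = NULL))
  }
  map <- agglomerate_features(selected, cut = cut, cap = cap)
  list(table = pool_agglomerates(selected, map), selection = sel, map = map)
}

# Seeded RNG scoping without a hard withr dependency: save/restore .Random.seed
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
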
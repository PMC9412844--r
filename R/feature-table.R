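#' @keywords internal
"_PACKAGE"

OMICS_TYPES <- c("microbiome", "volatilome", "metabolome_nmr")

#' Construct a feature table
#'
#' The universal data currency of the framework: a samples-by-features numeric
#' matrix carrying per-feature omics-type labels and unit tags. Sample ids are
#' row names, feature ids are column names; both must be unique.
#'
#' @param values Numeric matrix, samples in rows, features in columns, with
#'   complete dimnames.
#' @param feature_type Either a single omics type recycled over all features or
#'   a character vector (optionally named by feature id) with one of
#'   `"microbiome"`, `"volatilome"`, `"metabolome_nmr"` per feature.
#' @param units Per-feature unit tag (e.g. `"percent_RA"`, `"log_RA"`,
#'   `"intensity"`, `"pooled_intensity"`); a single string is recycled.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(values, feature_type, units = "intensity") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  # a table emptied by filtering has no features; colnames of a 0-column
  # matrix are necessarily NULL
  if (is.null(rownames(values)) ||
      (ncol(values) > 0 && is.null(colnames(values)))) {
    stop("`values` must have sample ids as rownames and feature ids as colnames",
         call. = FALSE)
  }
  fids <- if (ncol(values) == 0) character(0) else colnames(values)
  ft <- expand_per_feature(feature_type, fids, "feature_type")
  un <- expand_per_feature(units, fids, "units")
  x <- structure(list(values = values, feature_type = ft, units = un),
                 class = "feature_table")
  validate_feature_table(x)
  x
}

expand_per_feature <- function(x, ids, what) {
  if (length(x) == 1L) x <- rep(x, length(ids))
  if (length(x) != length(ids)) {
    stop(sprintf("`%s` must have length 1 or one entry per feature", what),
         call. = FALSE)
  }
  if (!is.null(names(x))) {
    missing <- setdiff(ids, names(x))
    if (length(missing) > 0) {
      stop(sprintf("`%s` missing entries for: %s", what,
                   paste(utils::head(missing, 5), collapse = ", ")),
           call. = FALSE)
    }
    x <- x[ids]
  } else {
    names(x) <- ids
  }
  x
}

validate_feature_table <- function(x) {
  stopifnot(inherits(x, "feature_table"))
  sid <- rownames(x$values)
  fid <- colnames(x$values)
  if (anyDuplicated(sid)) {
    stop("duplicate sample ids: ",
         paste(unique(sid[duplicated(sid)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(fid)) {
    stop("duplicate feature ids: ",
         paste(unique(fid[duplicated(fid)]), collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(x$feature_type), OMICS_TYPES)
  if (length(bad) > 0) {
    stop("unknown omics type(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$values), ncol(x$values)))
  tt <- table(x$feature_type)
  cat("  ", paste(sprintf("%s: %d", names(tt), tt), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

#' Sample and feature ids of a feature table
#' @param table A `feature_table`.
#' @return Character vector of ids.
#' @export
sample_ids <- function(table) rownames(table$values)

#' @rdname sample_ids
#' @export
feature_ids <- function(table) colnames(table$values)

#' Subset a feature table
#'
#' @param table A `feature_table`.
#' @param samples,features Character ids, logical mask or integer indices;
#'   `NULL` keeps everything.
#' @return A `feature_table`.
#' @export
subset_table <- function(table, samples = NULL, features = NULL) {
  validate_feature_table(table)
  if (is.null(samples)) samples <- seq_len(nrow(table$values))
  if (is.null(features)) features <- seq_len(ncol(table$values))
  v <- table$values[samples, features, drop = FALSE]
  feature_table(v, table$feature_type[colnames(v)], table$units[colnames(v)])
}

#' Merge omics blocks into one analysis table
#'
#' Concatenates feature blocks measured on the same samples. Blocks may list
#' samples in any order; rows are aligned by sample id to the order of the
#' first block. Feature ids must be disjoint across blocks.
#'
#' @param tables List of `feature_table`s over identical sample sets.
#' @param design Optional `sample_design` data frame; if supplied, every sample
#'   must have exactly one design row.
#' @return A merged `feature_table`.
#' @export
merge_tables <- function(tables, design = NULL) {
  stopifnot(is.list(tables), length(tables) >= 1)
  lapply(tables, validate_feature_table)
  ref <- sample_ids(tables[[1]])
  for (i in seq_along(tables)) {
    sid <- sample_ids(tables[[i]])
    if (!setequal(sid, ref) || length(sid) != length(ref)) {
      extra <- setdiff(sid, ref)
      miss <- setdiff(ref, sid)
      stop(sprintf(
        "sample sets differ between block 1 and block %d (only in %d: %s; missing from %d: %s)",
        i, i, paste(utils::head(extra, 5), collapse = ", "),
        i, paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
    }
  }
  all_feats <- unlist(lapply(tables, feature_ids))
  if (anyDuplicated(all_feats)) {
    stop("feature id collision across blocks: ",
         paste(unique(all_feats[duplicated(all_feats)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- do.call(cbind, lapply(tables, function(t) t$values[ref, , drop = FALSE]))
  ft <- do.call(c, lapply(tables, function(t) t$feature_type))
  un <- do.call(c, lapply(tables, function(t) t$units))
  out <- feature_table(vals, ft, un)
  if (!is.null(design)) check_design(out, design)
  out
}

#' Construct a sample design table
#'
#' One row per sample: subject id, sex (`F`/`M`), timepoint (`T0`/`Te`) and
#' intervention arm (`A` = active food product, `P` = placebo).
#'
#' @param sample_id,subject_id Character vectors.
#' @param sex,timepoint,arm Factors/characters with levels `F/M`, `T0/Te`,
#'   `A/P` respectively.
#' @return A data frame of class `sample_design`.
#' @export
sample_design <- function(sample_id, subject_id, sex, timepoint, arm) {
  d <- data.frame(sample_id = as.character(sample_id),
                  subject_id = as.character(subject_id),
                  sex = as.character(sex),
                  timepoint = as.character(timepoint),
                  arm = as.character(arm),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$sample_id)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  check_levels <- list(sex = c("F", "M"), timepoint = c("T0", "Te"),
                       arm = c("A", "P"))
  for (col in names(check_levels)) {
    bad <- setdiff(unique(d[[col]]), check_levels[[col]])
    if (length(bad) > 0) {
      stop(sprintf("invalid %s value(s): %s", col, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  class(d) <- c("sample_design", "data.frame")
  d
}

check_design <- function(table, design) {
  miss <- setdiff(sample_ids(table), design$sample_id)
  if (length(miss) > 0) {
    stop("samples without a design row: ",
         paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

# design rows aligned to a table's samples
design_for <- function(table, design) {
  check_design(table, design)
  design[match(sample_ids(table), design$sample_id), , drop = FALSE]
}
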
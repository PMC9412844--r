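# Delimited-text I/O for feature tables, design metadata and feature-type
# sidecars. Tables are samples-in-rows, features-in-columns; the delimiter is
# auto-detected among comma and tab unless given.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("empty file: ", path, call. = FALSE)
  n_tab <- lengths(regmatches(first, gregexpr("\t", first)))
  n_com <- lengths(regmatches(first, gregexpr(",", first)))
  if (n_tab >= n_com) "\t" else ","
}

#' Read a feature table from delimited text
#'
#' Expects a header row of feature ids and a first column of sample ids; the
#' body must be numeric. Non-numeric cells raise a parse error naming the
#' offending row and column; duplicated ids raise a validation error.
#'
#' @param path File path (CSV or TSV).
#' @param omics_type Omics type assigned to every feature in the file.
#' @param units Unit tag for every feature.
#' @param delim Field delimiter; `NULL` auto-detects among `","` and `"\t"`.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, omics_type, units = "intensity",
                               delim = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(delim)) delim <- detect_delim(path)
  raw <- utils::read.table(path, sep = delim, header = FALSE,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (nrow(raw) < 2 || ncol(raw) < 2) {
    stop("feature table needs a header row and at least one sample row: ",
         path, call. = FALSE)
  }
  fids <- as.character(raw[1, -1])
  sids <- as.character(raw[-1, 1])
  if (anyDuplicated(fids)) {
    stop("duplicate feature id(s) in header: ",
         paste(unique(fids[duplicated(fids)]), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(sids)) {
    stop("duplicate sample id(s): ",
         paste(unique(sids[duplicated(sids)]), collapse = ", "), call. = FALSE)
  }
  body <- as.matrix(raw[-1, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) & !(trimws(body) %in% c("NA", "NaN")), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric value \"%s\" at sample \"%s\", feature \"%s\"",
                 body[bad[1, 1], bad[1, 2]], sids[bad[1, 1]], fids[bad[1, 2]]),
         call. = FALSE)
  }
  dimnames(num) <- list(sids, fids)
  feature_table(num, omics_type, units)
}

#' Write a feature table to delimited text
#'
#' @param table A `feature_table`.
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, delim = ",") {
  validate_feature_table(table)
  df <- data.frame(sample_id = sample_ids(table), table$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Read/write the feature-type sidecar
#'
#' Feature-type labels travel in a sidecar TSV (`feature_id`, `omics_type`,
#' `display_name`) rather than being encoded in feature ids, keeping ids safe
#' for graph formats.
#'
#' @param path TSV path.
#' @return For the reader, a data frame with the three sidecar columns.
#' @export
read_feature_types <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("feature_id", "omics_type")
  if (!all(need %in% names(d))) {
    stop("sidecar must have columns feature_id and omics_type", call. = FALSE)
  }
  if (!"display_name" %in% names(d)) d$display_name <- d$feature_id
  bad <- setdiff(unique(d$omics_type), OMICS_TYPES)
  if (length(bad) > 0) {
    stop("unknown omics type(s) in sidecar: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  d
}

#' @rdname read_feature_types
#' @param table A `feature_table` whose labels should be written.
#' @export
write_feature_types <- function(table, path) {
  d <- data.frame(feature_id = feature_ids(table),
                  omics_type = unname(table$feature_type),
                  display_name = feature_ids(table),
                  stringsAsFactors = FALSE)
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write sample design metadata
#'
#' TSV with columns `sample_id`, `subject_id`, `sex`, `timepoint`, `arm`.
#'
#' @param path TSV path.
#' @return A [sample_design()] data frame.
#' @export
read_sample_design <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character")
  need <- c("sample_id", "subject_id", "sex", "timepoint", "arm")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("design metadata missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sample_design(d$sample_id, d$subject_id, d$sex, d$timepoint, d$arm)
}

#' @rdname read_sample_design
#' @param design A `sample_design`.
#' @export
write_sample_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resolve missing values before correlation
#'
#' Missing values are tolerated on read but must be resolved before any
#' correlation is computed. The default policy is a hard error; `"drop"`
#' removes features containing `NA`s (logged in the `removed` attribute).
#'
#' @param table A `feature_table`.
#' @param policy `"error"` (default) or `"drop"`.
#' @return A `feature_table` free of missing values.
#' @export
resolve_missing <- function(table, policy = c("error", "drop")) {
  policy <- match.arg(policy)
  validate_feature_table(table)
  na_feat <- colnames(table$values)[colSums(is.na(table$values)) > 0]
  if (length(na_feat) == 0) return(table)
  if (policy == "error") {
    stop("missing values in feature(s): ",
         paste(utils::head(na_feat, 5), collapse = ", "),
         "; resolve them (policy = \"drop\") before correlation",
         call. = FALSE)
  }
  out <- subset_table(table, features = setdiff(feature_ids(table), na_feat))
  attr(out, "removed") <- na_feat
  out
}

#' Optional z-score outlier screen
#'
#' Flags cells whose within-feature z-score exceeds `z_max` and sets them to
#' `NA` for downstream resolution. Exposed as an optional screen because
#' upstream outlier handling has no single accepted rule.
#'
#' @param table A `feature_table`.
#' @param z_max Threshold on |z| (default 4).
#' @return A `feature_table` with flagged cells set to `NA`; the count is in
#'   attribute `n_outliers`.
#' @export
screen_outliers <- function(table, z_max = 4) {
  validate_feature_table(table)
  v <- table$values
  z <- scale(v)
  mask <- !is.na(z) & abs(z) > z_max
  v[mask] <- NA_real_
  out <- feature_table(v, table$feature_type, table$units)
  attr(out, "n_outliers") <- sum(mask)
  out
}
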
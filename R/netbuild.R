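# Spearman correlation matrices and binary threshold networks per subject
# group (sex at baseline; sex x arm at endpoint).

#' Spearman correlation matrix of a feature table
#'
#' Rank correlation captures any monotone relationship between features, which
#' is what a link in the network represents. Ties receive average ranks.
#' Zero-variance features have undefined correlations; their entries are set
#' to 0 with a warning (no link can form) and their ids recorded in attribute
#' `zero_variance`.
#'
#' @param table A `feature_table` with at least 3 samples and no missing
#'   values.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(table) {
  validate_feature_table(table)
  v <- table$values
  if (nrow(v) < 3) stop("need at least 3 samples", call. = FALSE)
  if (anyNA(v)) {
    stop("missing values present; resolve them first (see resolve_missing)",
         call. = FALSE)
  }
  sds <- apply(v, 2, stats::sd)
  zv <- colnames(v)[sds == 0]
  rho <- suppressWarnings(stats::cor(v, method = "spearman"))
  if (length(zv) > 0) {
    warning("zero-variance feature(s), correlations set to 0: ",
            paste(utils::head(zv, 5), collapse = ", "), call. = FALSE)
    rho[zv, ] <- 0
    rho[, zv] <- 0
  }
  diag(rho) <- 1
  attr(rho, "zero_variance") <- zv
  attr(rho, "n_samples") <- nrow(v)
  rho
}

#' Threshold policies for link generation
#'
#' `fixed` uses a hard correlation threshold `t`; `significance` resolves the
#' threshold to the minimum correlation significant at level `alpha` for the
#' group's sample size; `soft` designates WGCNA-style soft thresholding,
#' which yields a weight power rather than a binary cutoff and is served by
#' [soft_threshold_power()] as a diagnostic (it cannot resolve to a binary
#' adjacency).
#'
#' @param t Fixed threshold in `(-1, 1]`.
#' @param alpha Significance level (default 0.05).
#' @param powers Candidate powers for the soft policy.
#' @return A `threshold_policy` object.
#' @export
fixed_policy <- function(t) {
  stopifnot(is.numeric(t), length(t) == 1, t > -1, t <= 1)
  structure(list(kind = "fixed", t = t), class = "threshold_policy")
}

#' @rdname fixed_policy
#' @export
significance_policy <- function(alpha = 0.05) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  structure(list(kind = "significance", alpha = alpha),
            class = "threshold_policy")
}

#' @rdname fixed_policy
#' @export
soft_policy <- function(powers = 1:20) {
  structure(list(kind = "soft", powers = as.integer(powers)),
            class = "threshold_policy")
}

#' Minimum correlation significant at a given level
#'
#' The smallest rho whose two-sided p-value under the Spearman t
#' approximation, `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom, falls below `alpha`. The p-value is strictly decreasing in
#' rho, so the threshold is found by root-finding (tolerance 1e-9). Because
#' significance tightens with sample size, the threshold decreases in `n`:
#' larger baseline groups admit a softer threshold than the smaller
#' per-arm endpoint groups.
#'
#' @param n Sample count (>= 4).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The threshold rho in (0, 1).
#' @export
min_significant_threshold <- function(n, alpha = 0.05) {
  stopifnot(is.numeric(n), length(n) == 1)
  n <- as.integer(n)
  if (n < 4) stop("need n >= 4 for a usable correlation test", call. = FALSE)
  stopifnot(alpha > 0, alpha < 1)
  pfun <- function(rho) {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  stats::uniroot(function(r) pfun(r) - alpha, lower = 1e-12,
                 upper = 1 - 1e-12, tol = 1e-9)$root
}

#' Spearman p-value by seeded permutation (small-sample alternative)
#'
#' For very small groups the t approximation is rough; this computes a
#' permutation p-value for the observed Spearman correlation of two vectors.
#'
#' @param x,y Numeric vectors of equal length.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed.
#' @return Two-sided permutation p-value.
#' @export
spearman_perm_pvalue <- function(x, y, n_perm = 9999, seed = 1) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  obs <- stats::cor(x, y, method = "spearman")
  rs <- local_rng(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    r <- stats::cor(x, sample(y), method = "spearman")
    if (abs(r) >= abs(obs) - 1e-12) hits <- hits + 1L
  }
  restore_rng(rs)
  (hits + 1) / (n_perm + 1)
}

#' Build a binary correlation network
#'
#' A link between two features exists iff their Spearman correlation exceeds
#' the threshold, strictly: `rho > t` in `signed` mode (the default reading
#' of "correlation greater than t") or `|rho| > t` in `absolute` mode
#' (anti-correlations, e.g. competitive exclusion between taxa, can be
#' biologically meaningful). The result is the binary Nfeats x Nfeats
#' adjacency with zero diagonal, wrapped as an undirected, unweighted graph;
#' isolated features stay as nodes.
#'
#' @param corr Symmetric correlation matrix with unit diagonal (e.g. from
#'   [spearman_matrix()]).
#' @param t Threshold in `(-1, 1]`.
#' @param types Named character of omics types per feature; defaults to the
#'   dimnames of `corr` looked up as `"microbiome"` (only used for node
#'   attributes, so any named vector covering the features works).
#' @param mode `"signed"` (default) or `"absolute"`.
#' @param group Group descriptor stored in provenance.
#' @param n_samples Sample count stored in provenance.
#' @return An `omics_network`: a list with the `igraph` graph and a
#'   `provenance` record (group, n_samples, t, mode, method).
#' @export
build_network <- function(corr, t, types = NULL,
                          mode = c("signed", "absolute"),
                          group = NA_character_, n_samples = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (max(abs(corr - t(corr))) > 1e-8) {
    stop("correlation matrix must be symmetric", call. = FALSE)
  }
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- paste0("f", seq_len(nrow(corr)))
  }
  ids <- rownames(corr)
  if (is.null(types)) {
    types <- stats::setNames(rep("microbiome", length(ids)), ids)
  }
  types <- expand_per_feature(types, ids, "types")
  if (t >= 1 && mode == "signed") {
    warning("threshold >= 1 with strict inequality yields an empty edge set",
            call. = FALSE)
  }
  adj <- if (mode == "signed") corr > t else abs(corr) > t
  adj[!is.finite(corr)] <- FALSE
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  igraph::V(g)$omics_type <- unname(types[igraph::V(g)$name])
  if (is.na(n_samples) && !is.null(attr(corr, "n_samples"))) {
    n_samples <- attr(corr, "n_samples")
  }
  structure(list(graph = g,
                 provenance = list(group = group,
                                   n_samples = as.integer(n_samples),
                                   t = t, mode = mode,
                                   method = "spearman")),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  p <- x$provenance
  cat(sprintf(
    "<omics_network> %d nodes, %d edges (group %s, n = %s, t = %.4g, %s)\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph),
    ifelse(is.na(p$group), "-", p$group),
    ifelse(is.na(p$n_samples), "-", p$n_samples), p$t, p$mode))
  invisible(x)
}

#' Accessors for omics networks
#' @param net An `omics_network`.
#' @return `network_nodes`: data frame of node ids and omics types;
#'   `network_edges`: two-column character matrix of edges with ends sorted
#'   within each row; `adjacency_matrix`: the binary 0/1 matrix with zero
#'   diagonal.
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "omics_network"))
  data.frame(id = igraph::V(net$graph)$name,
             omics_type = igraph::V(net$graph)$omics_type,
             stringsAsFactors = FALSE)
}

#' @rdname network_nodes
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "omics_network"))
  e <- igraph::as_edgelist(net$graph)
  if (nrow(e) > 0) {
    e <- t(apply(e, 1, sort))
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  colnames(e) <- c("source", "target")
  e
}

#' @rdname network_nodes
#' @export
adjacency_matrix <- function(net) {
  stopifnot(inherits(net, "omics_network"))
  m <- as.matrix(igraph::as_adjacency_matrix(net$graph))
  storage.mode(m) <- "integer"
  m
}

default_group_policies <- function(groups) {
  pol <- list()
  for (g in groups) {
    pol[[g]] <- if (startsWith(g, "T0")) fixed_policy(0.5) else fixed_policy(0.7)
  }
  pol
}

#' Build one network per subject group
#'
#' Groups follow the trial structure: at baseline (T0) samples are split by
#' sex only, pooling the arms (the intervention has not started and the
#' larger sample admits the softer default threshold of 0.5); at endpoint
#' (Te) samples are split by sex and arm, with the harder default threshold
#' of 0.7 compensating the smaller per-group sample. Each group's policy is
#' resolved to a numeric threshold recorded in the network's provenance.
#'
#' @param table A merged `feature_table` holding samples from both
#'   timepoints.
#' @param design A [sample_design()] covering the table's samples.
#' @param policies Named list mapping group labels (`"T0_F"`, `"T0_M"`,
#'   `"Te_F_A"`, ...) to [fixed_policy()] or [significance_policy()];
#'   defaults to fixed 0.5 at T0 and fixed 0.7 at Te.
#' @param mode Thresholding mode passed to [build_network()].
#' @return Named list of `omics_network`s, one per group present in the
#'   design.
#' @export
apply_group_policy <- function(table, design, policies = NULL,
                               mode = c("signed", "absolute")) {
  mode <- match.arg(mode)
  validate_feature_table(table)
  d <- design_for(table, design)
  groups <- list()
  for (sex in intersect(c("F", "M"), unique(d$sex))) {
    rows <- d$timepoint == "T0" & d$sex == sex
    if (any(rows)) groups[[paste0("T0_", sex)]] <- which(rows)
    arms_here <- intersect(c("A", "P"), unique(d$arm[d$timepoint == "Te" & d$sex == sex]))
    for (arm in arms_here) {
      rows <- d$timepoint == "Te" & d$sex == sex & d$arm == arm
      if (any(rows)) groups[[paste0("Te_", sex, "_", arm)]] <- which(rows)
    }
    if (length(arms_here) == 1) {
      warning(sprintf("only one arm present at Te for sex %s", sex),
              call. = FALSE)
    }
  }
  if (length(groups) == 0) stop("no groups found in design", call. = FALSE)
  pol <- default_group_policies(names(groups))
  if (!is.null(policies)) pol[names(policies)] <- policies
  nets <- list()
  for (g in names(groups)) {
    rows <- groups[[g]]
    if (length(rows) < 4) {
      stop(sprintf("group %s has %d sample(s); need >= 4 for correlation",
                   g, length(rows)), call. = FALSE)
    }
    sub <- subset_table(table, samples = rows)
    rho <- spearman_matrix(sub)
    p <- pol[[g]]
    stopifnot(inherits(p, "threshold_policy"))
    t_num <- switch(p$kind,
      fixed = p$t,
      significance = min_significant_threshold(length(rows), p$alpha),
      stop(sprintf(
        "policy kind \"%s\" cannot resolve to a binary threshold for group %s",
        p$kind, g), call. = FALSE))
    nets[[g]] <- build_network(rho, t_num, types = table$feature_type,
                               mode = mode, group = g,
                               n_samples = length(rows))
    nets[[g]]$provenance$policy <- p$kind
  }
  nets
}

#' Soft-threshold power for approximate scale-free topology
#'
#' The WGCNA-style alternative to hard thresholding: correlations are raised
#' to a power and the power is chosen so the weighted connectivities
#' `k_i = sum_j |rho_ij|^beta` best follow a power-law (scale-free) degree
#' distribution. The fit index is the R-squared of the regression of
#' log10(frequency) on log10(k) over connectivity bins.
#'
#' @param corr Correlation matrix.
#' @param powers Candidate integer powers (subset of 1..30).
#' @param rsq_target Return the smallest power whose fit index reaches this
#'   value (default 0.8); if none does, the argmax power is returned.
#' @param n_bins Number of connectivity bins (default 10).
#' @return A list with `power`, `fit_table` (power, rsq, slope, mean_k) and
#'   `rsq_target`.
#' @export
soft_threshold_power <- function(corr, powers = 1:20, rsq_target = 0.8,
                                 n_bins = 10) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  powers <- sort(unique(as.integer(powers)))
  stopifnot(all(powers >= 1), all(powers <= 30))
  a <- abs(corr)
  diag(a) <- 0
  if (max(a) == 0) {
    stop("all off-diagonal correlations are zero", call. = FALSE)
  }
  rows <- lapply(powers, function(b) {
    k <- rowSums(a^b)
    c(power = b, rsq = scale_free_fit_rsq(k, n_bins = n_bins)["rsq"],
      slope = scale_free_fit_rsq(k, n_bins = n_bins)["slope"],
      mean_k = mean(k))
  })
  tab <- as.data.frame(do.call(rbind, rows))
  names(tab) <- c("power", "rsq", "slope", "mean_k")
  ok <- which(!is.na(tab$rsq) & tab$rsq >= rsq_target)
  chosen <- if (length(ok) > 0) {
    tab$power[ok[1]]
  } else {
    tab$power[which.max(tab$rsq)]
  }
  list(power = as.integer(chosen), fit_table = tab, rsq_target = rsq_target)
}

# R^2 of log10(freq) ~ log10(mean k) over equal-width connectivity bins
scale_free_fit_rsq <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < 3 || length(unique(k)) < 3) {
    return(c(rsq = NA_real_, slope = NA_real_))
  }
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  br[1] <- br[1] - 1e-9
  bin <- cut(k, br)
  cnt <- tapply(k, bin, length)
  mid <- tapply(k, bin, mean)
  use <- !is.na(cnt) & cnt > 0 & mid > 0
  if (sum(use) < 3) return(c(rsq = NA_real_, slope = NA_real_))
  x <- log10(mid[use])
  y <- log10(cnt[use] / sum(cnt[use]))
  fit <- stats::lm(y ~ x)
  c(rsq = summary(fit)$r.squared, slope = unname(stats::coef(fit)[2]))
}
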
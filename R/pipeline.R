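# End-to-end orchestration: preprocess each omics block, reduce the NMR
# block, merge, build per-group networks, summarise topology, detect
# communities and compare groups. Every numeric decision (thresholds, cut
# heights, chosen penalties) lands in the manifest; nothing is silent.

#' Run the full analysis pipeline
#'
#' Executes filter -> log transform -> NMR reduction -> merge -> per-group
#' network construction -> topology -> k-clique communities -> cross-group
#' comparisons on tables holding both timepoints. The NMR reduction is
#' fitted once on all samples so baseline and endpoint networks share the
#' same node set (the same features are compared at T0 and Te). Identical
#' inputs and seed give identical outputs.
#'
#' @param t0,te Merged `feature_table`s (taxa RA%, VOC RA%, NMR buckets) for
#'   baseline and endpoint, e.g. from [simulate_cohort()] or built with
#'   [merge_tables()] from files.
#' @param design A [sample_design()] covering both tables' samples.
#' @param filter_cfg A [filter_config()] applied to the microbiome and
#'   volatilome blocks.
#' @param pseudocount Passed to [log_transform()] (`NULL` = automatic).
#' @param nmr_labels Which design columns label classes for bucket selection:
#'   character vector out of `"arm"`, `"timepoint"`, `"sex"` (default
#'   `c("arm", "timepoint")`, i.e. the intervention outcomes).
#' @param folds,lambda_grid,cut,cap NMR-reduction settings (see
#'   [reduce_nmr()]).
#' @param policies Per-group threshold policies (see [apply_group_policy()]).
#' @param mode Thresholding mode, `"signed"` or `"absolute"`.
#' @param k_values Community orders to detect (default `c(3, 4)`).
#' @param min_jaccard Community-matching threshold.
#' @param seed Top-level seed; per-stage seeds are derived from it
#'   deterministically.
#' @param out_dir If non-`NULL`, networks (GraphML + edge list), reports
#'   (JSON) and the manifest are written there.
#' @return A `pipeline_result` list: `tables` (per-block processed and merged
#'   tables), `reduction`, `networks`, `topology`, `communities` (nested
#'   group -> k), `comparisons` and `manifest`.
#' @export
run_pipeline <- function(t0, te, design,
                         filter_cfg = filter_config(),
                         pseudocount = NULL,
                         nmr_labels = c("arm", "timepoint"),
                         folds = 5, lambda_grid = NULL,
                         cut = "auto", cap = 0.7,
                         policies = NULL,
                         mode = c("signed", "absolute"),
                         k_values = c(3, 4),
                         min_jaccard = 0.5,
                         seed = 1,
                         out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(k_values >= 2))
  validate_feature_table(t0)
  validate_feature_table(te)
  check_design(t0, design)
  check_design(te, design)
  # per-stage seeds derived from the top-level seed (kept below 2^31)
  stage_seed <- function(stage) {
    (seed * 1000L + sum(utf8ToInt(stage))) %% .Machine$integer.max
  }

  both <- stack_timepoints(t0, te)
  d_both <- design_for(both, design)

  split_tab <- function(type) {
    keep <- which(both$feature_type == type)
    subset_table(both, features = keep)
  }

  processed <- list()
  removed <- list()
  for (type in c("microbiome", "volatilome")) {
    block <- split_tab(type)
    if (ncol(block$values) == 0) next
    filt <- filter_by_median_abundance(block, filter_cfg, design)
    removed[[type]] <- attr(filt, "removed")
    if (isTRUE(attr(filt, "empty"))) {
      warning(sprintf("%s block is empty after filtering; block dropped", type),
              call. = FALSE)
      next
    }
    processed[[type]] <- log_transform(filt, pseudocount)
  }

  reduction <- NULL
  nmr_block <- split_tab("metabolome_nmr")
  if (ncol(nmr_block$values) > 0) {
    labels <- interaction(d_both[, nmr_labels, drop = FALSE], drop = TRUE)
    reduction <- reduce_nmr(log_transform(nmr_block, pseudocount),
                            labels, folds = folds,
                            lambda_grid = lambda_grid, cut = cut, cap = cap,
                            seed = stage_seed("nmr_reduce"))
    if (ncol(reduction$table$values) > 0) {
      processed[["metabolome_nmr"]] <- reduction$table
    }
  }
  if (length(processed) == 0) {
    stop("pipeline stage merge: no features survived preprocessing",
         call. = FALSE)
  }
  merged <- merge_tables(unname(processed), design)

  networks <- apply_group_policy(merged, design, policies = policies,
                                 mode = mode)
  topology <- lapply(networks, topology_report)
  communities <- lapply(networks, function(net) {
    out <- lapply(k_values, function(k) k_clique_communities(net, k))
    names(out) <- paste0("k", k_values)
    out
  })

  comparisons <- list()
  k_cmp <- k_values[1]
  for (sex in c("F", "M")) {
    pairs <- list(
      c(paste0("Te_", sex, "_A"), paste0("Te_", sex, "_P")),
      c(paste0("T0_", sex), paste0("Te_", sex, "_A")),
      c(paste0("T0_", sex), paste0("Te_", sex, "_P")))
    for (p in pairs) {
      if (all(p %in% names(networks))) {
        comparisons[[paste(p, collapse = "_vs_")]] <-
          compare_networks(networks[[p[1]]], networks[[p[2]]], k = k_cmp,
                           min_jaccard = min_jaccard)
      }
    }
  }

  manifest <- list(
    parameters = list(
      filter = unclass(filter_cfg),
      pseudocount = if (is.null(pseudocount)) "auto" else pseudocount,
      nmr_labels = nmr_labels, folds = folds,
      cut = if (identical(cut, "auto")) "auto" else cut, cap = cap,
      mode = mode, k_values = k_values, min_jaccard = min_jaccard,
      seed = seed),
    removed_features = removed,
    nmr = if (!is.null(reduction)) list(
      n_buckets_in = ncol(nmr_block$values),
      n_selected = length(reduction$selection$kept_feature_ids),
      chosen_lambda = reduction$selection$optimizer_trace$chosen_lambda,
      cut_height = if (!is.null(reduction$map)) reduction$map$cut_height else NA,
      n_agglomerates = ncol(reduction$table$values),
      seed = reduction$selection$optimizer_trace$seed),
    n_features_merged = ncol(merged$values),
    networks = lapply(networks, function(net) {
      c(net$provenance,
        list(n_nodes = igraph::vcount(net$graph),
             n_edges = igraph::ecount(net$graph)))
    }),
    communities = lapply(communities, function(by_k) {
      lapply(by_k, function(cs) {
        list(n_communities = length(cs$communities),
             sizes = lengths(cs$communities),
             n_bridge_nodes = sum(cs$membership >= 2))
      })
    }),
    comparisons = lapply(comparisons, function(cmp) {
      list(edge_jaccard = cmp$edge_jaccard,
           n_matched = nrow(cmp$matching$matches),
           n_unmatched_a = length(cmp$matching$unmatched_a),
           n_unmatched_b = length(cmp$matching$unmatched_b))
    }))

  result <- structure(list(tables = c(processed, list(merged = merged)),
                           reduction = reduction, networks = networks,
                           topology = topology, communities = communities,
                           comparisons = comparisons, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d features merged, %d networks (%s)\n",
              x$manifest$n_features_merged, length(x$networks),
              paste(names(x$networks), collapse = ", ")))
  invisible(x)
}

# one table holding the samples of both timepoints (shared feature set)
stack_timepoints <- function(t0, te) {
  if (!setequal(feature_ids(t0), feature_ids(te))) {
    stop("T0 and Te tables must share the same feature set", call. = FALSE)
  }
  fids <- feature_ids(t0)
  vals <- rbind(t0$values, te$values[, fids, drop = FALSE])
  feature_table(vals, t0$feature_type[fids], t0$units[fids])
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- result$manifest
  manifest$artifacts <- list()
  # manifest records artifact names relative to out_dir so identical runs
  # into different directories produce byte-identical manifests
  for (g in names(result$networks)) {
    gml <- paste0("net_", g, ".graphml")
    edg <- paste0("net_", g, ".edges.tsv")
    export_network(result$networks[[g]], file.path(out_dir, gml), "graphml")
    export_network(result$networks[[g]], file.path(out_dir, edg), "edgelist")
    topo <- paste0("topology_", g, ".json")
    write_topology_report(result$topology[[g]], file.path(out_dir, topo))
    manifest$artifacts[[g]] <- c(gml, edg, topo)
    for (kname in names(result$communities[[g]])) {
      cj <- paste0("communities_", g, "_", kname, ".json")
      write_community_report(result$communities[[g]][[kname]],
                             file.path(out_dir, cj))
      manifest$artifacts[[g]] <- c(manifest$artifacts[[g]], cj)
    }
  }
  if (!is.null(result$reduction$map)) {
    am <- "agglomeration_map.json"
    write_agglomeration_map(result$reduction$map, file.path(out_dir, am))
    manifest$artifacts$agglomeration <- am
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
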
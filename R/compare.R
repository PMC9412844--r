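# Cross-group comparison: topology deltas, edge-set overlap, one-to-one
# community matching and bridge-node shifts. "Extension" of a community is
# its node-set size; "completeness" of a matched pair is the fraction of the
# partner's nodes present.

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)  # two empty sets are identical
  length(intersect(a, b)) / u
}

edge_keys <- function(net) {
  e <- network_edges(net)
  if (nrow(e) == 0) return(character(0))
  paste(e[, 1], e[, 2], sep = "|")
}

#' Match communities across two community sets
#'
#' Greedy maximum-Jaccard one-to-one matching between the communities of two
#' groups at the same order k. The globally best remaining pair is matched
#' first (ties broken by larger intersection, then canonical order); pairs
#' whose best Jaccard falls below `min_jaccard` are reported unmatched. For
#' each matched pair the nodes missing in either group are listed, exposing
#' "similar communities with different completeness".
#'
#' @param a,b `community_set`s with the same `k`.
#' @param min_jaccard Minimal Jaccard similarity for a match (default 0.5).
#' @return A list of class `community_matching`: `matches` data frame
#'   (`community_a`, `community_b`, `jaccard`, `n_shared`,
#'   `completeness_a`, `completeness_b`, `shared`, `missing_in_a`,
#'   `missing_in_b`), `unmatched_a`, `unmatched_b` (community indices) and
#'   `k`.
#' @export
match_communities <- function(a, b, min_jaccard = 0.5) {
  stopifnot(inherits(a, "community_set"), inherits(b, "community_set"))
  if (a$k != b$k) {
    stop(sprintf("community sets have different orders (k = %d vs %d)",
                 a$k, b$k), call. = FALSE)
  }
  na <- length(a$communities)
  nb <- length(b$communities)
  J <- matrix(0, na, nb)
  X <- matrix(0L, na, nb)
  if (na > 0 && nb > 0) {
    for (i in seq_len(na)) {
      for (j in seq_len(nb)) {
        X[i, j] <- length(intersect(a$communities[[i]], b$communities[[j]]))
        J[i, j] <- jaccard(a$communities[[i]], b$communities[[j]])
      }
    }
  }
  rows <- list()
  free_a <- rep(TRUE, na)
  free_b <- rep(TRUE, nb)
  while (any(free_a) && any(free_b)) {
    Jm <- J
    Jm[!free_a, ] <- -Inf
    Jm[, !free_b] <- -Inf
    best <- max(Jm)
    if (!is.finite(best) || best < min_jaccard) break
    cand <- which(Jm >= best - 1e-12, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      xs <- X[cand]
      cand <- cand[xs == max(xs), , drop = FALSE]
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    }
    i <- cand[1, 1]
    j <- cand[1, 2]
    ca <- a$communities[[i]]
    cb <- b$communities[[j]]
    sh <- intersect(ca, cb)
    rows[[length(rows) + 1]] <- data.frame(
      community_a = i, community_b = j,
      jaccard = J[i, j], n_shared = length(sh),
      completeness_a = length(sh) / length(cb),
      completeness_b = length(sh) / length(ca),
      shared = paste(sh, collapse = ";"),
      missing_in_a = paste(setdiff(cb, ca), collapse = ";"),
      missing_in_b = paste(setdiff(ca, cb), collapse = ";"),
      stringsAsFactors = FALSE)
    free_a[i] <- FALSE
    free_b[j] <- FALSE
  }
  matches <- if (length(rows) > 0) {
    do.call(rbind, rows)
  } else {
    data.frame(community_a = integer(0), community_b = integer(0),
               jaccard = numeric(0), n_shared = integer(0),
               completeness_a = numeric(0), completeness_b = numeric(0),
               shared = character(0), missing_in_a = character(0),
               missing_in_b = character(0), stringsAsFactors = FALSE)
  }
  structure(list(matches = matches,
                 unmatched_a = which(free_a),
                 unmatched_b = which(free_b),
                 k = a$k, min_jaccard = min_jaccard),
            class = "community_matching")
}

#' @export
print.community_matching <- function(x, ...) {
  cat(sprintf(
    "<community_matching> k = %d: %d matched pair(s), %d/%d unmatched\n",
    x$k, nrow(x$matches), length(x$unmatched_a), length(x$unmatched_b)))
  invisible(x)
}

#' Compare two omics networks
#'
#' Bundles the comparison criteria for two groups: per-field topology deltas
#' (`a` minus `b`), edge-set Jaccard similarity, community matching at order
#' `k` and per-node differences in community membership counts (bridge
#' deltas). Networks are expected over the same node universe; otherwise the
#' union is taken with a warning.
#'
#' @param a,b `omics_network`s.
#' @param k Community order for the matching (default 3).
#' @param min_jaccard Matching threshold passed to [match_communities()].
#' @return A `comparison_report` list: `topology_a`, `topology_b`,
#'   `topology_delta`, `edge_jaccard`, `communities_a`, `communities_b`,
#'   `matching`, `bridge_delta` (named per-node membership difference for
#'   nodes whose membership differs).
#' @export
compare_networks <- function(a, b, k = 3, min_jaccard = 0.5) {
  stopifnot(inherits(a, "omics_network"), inherits(b, "omics_network"))
  va <- igraph::V(a$graph)$name
  vb <- igraph::V(b$graph)$name
  if (!setequal(va, vb)) {
    warning("networks cover different node sets; comparing on the union",
            call. = FALSE)
  }
  universe <- sort(union(va, vb))
  ea <- edge_keys(a)
  eb <- edge_keys(b)
  ta <- topology_report(a)
  tb <- topology_report(b)
  num_fields <- c("n_nodes", "n_edges", "density", "avg_degree",
                  "avg_clustering", "n_components", "n_isolated")
  delta <- stats::setNames(
    vapply(num_fields, function(f) as.numeric(ta[[f]]) - as.numeric(tb[[f]]),
           numeric(1)),
    num_fields)
  ca <- k_clique_communities(a, k)
  cb <- k_clique_communities(b, k)
  mem_a <- stats::setNames(integer(length(universe)), universe)
  mem_b <- mem_a
  mem_a[names(ca$membership)] <- ca$membership
  mem_b[names(cb$membership)] <- cb$membership
  bd <- mem_a - mem_b
  structure(list(
    topology_a = ta, topology_b = tb, topology_delta = delta,
    edge_jaccard = jaccard(ea, eb),
    communities_a = ca, communities_b = cb,
    matching = match_communities(ca, cb, min_jaccard = min_jaccard),
    bridge_delta = bd[bd != 0]
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  cat(sprintf("  edge jaccard %.3f | delta edges %+g | delta density %+.3f\n",
              x$edge_jaccard, x$topology_delta["n_edges"],
              x$topology_delta["density"]))
  print(x$matching)
  invisible(x)
}
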
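# Overlapping community detection by clique percolation. A k-clique
# community is the union of all k-cliques reachable from one another through
# chains of adjacent k-cliques sharing k-1 nodes; communities may overlap,
# and nodes in several communities (bridge nodes) tie distinct biochemical
# mechanisms together.

#' Enumerate maximal cliques
#'
#' Every maximal clique of the network, each once, none a subset of another
#' (Bron-Kerbosch with pivoting, via igraph). A hard cap guards against
#' pathological dense graphs whose clique count explodes.
#'
#' @param net An `omics_network` or `igraph` graph.
#' @param min_size Only return cliques with at least this many nodes.
#' @param max_cliques Abort if the graph holds more maximal cliques than this
#'   (default 1e6).
#' @return List of character vectors (sorted node names), in canonical order.
#' @export
enumerate_maximal_cliques <- function(net, min_size = 1, max_cliques = 1e6) {
  g <- if (inherits(net, "omics_network")) net$graph else net
  stopifnot(inherits(g, "igraph"))
  g <- named_graph(g)
  n_cl <- igraph::count_max_cliques(g, min = min_size)
  if (n_cl > max_cliques) {
    stop(sprintf(
      "graph has %g maximal cliques, above the cap of %g; it is too dense for clique percolation",
      n_cl, max_cliques), call. = FALSE)
  }
  cl <- igraph::max_cliques(g, min = min_size)
  out <- lapply(cl, function(x) sort(igraph::V(g)$name[as.integer(x)]))
  canonical_setlist(out)
}

named_graph <- function(g) {
  if (!"name" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  }
  g
}

# sort a list of sorted node-id vectors lexicographically (size-stable)
canonical_setlist <- function(sets) {
  if (length(sets) == 0) return(sets)
  keys <- vapply(sets, paste, character(1), collapse = "\r")
  sets[order(keys)]
}

#' Detect k-clique communities by clique percolation
#'
#' Implemented over maximal cliques of size >= k: two maximal cliques are
#' adjacent when they share at least k-1 nodes, and each community is the
#' node union of one connected component of that clique adjacency. This is
#' the standard equivalent shortcut to percolating all k-cliques directly
#' (every k-clique lies inside a maximal clique, and any two k-cliques inside
#' one maximal clique of size >= k already share k-1 nodes when k >= 2).
#' Nodes in no k-clique belong to no community. `k` acts as a zooming
#' parameter: higher orders resolve only the most densely interconnected
#' consortia.
#'
#' @param net An `omics_network` or `igraph` graph.
#' @param k Community order (>= 2); `k = 2` gives the connected components
#'   restricted to non-isolated nodes.
#' @param max_cliques Cap passed to [enumerate_maximal_cliques()].
#' @return A `community_set`: `k`, `communities` (list of sorted node-id
#'   vectors in canonical order), `membership` (named counts over all
#'   network nodes) and `feature_type` (named omics types, when available).
#' @export
k_clique_communities <- function(net, k, max_cliques = 1e6) {
  g <- if (inherits(net, "omics_network")) net$graph else net
  stopifnot(inherits(g, "igraph"))
  g <- named_graph(g)
  k <- as.integer(k)
  if (k < 2) stop("`k` must be >= 2", call. = FALSE)
  nodes <- igraph::V(g)$name
  types <- if ("omics_type" %in% igraph::vertex_attr_names(g)) {
    stats::setNames(igraph::V(g)$omics_type, nodes)
  } else {
    NULL
  }
  mc <- enumerate_maximal_cliques(g, min_size = k, max_cliques = max_cliques)
  comms <- list()
  if (length(mc) > 0) {
    # clique x node incidence; cliques adjacent iff they share >= k-1 nodes
    all_n <- sort(unique(unlist(mc)))
    inc <- matrix(0L, length(mc), length(all_n),
                  dimnames = list(NULL, all_n))
    for (i in seq_along(mc)) inc[i, mc[[i]]] <- 1L
    shared <- tcrossprod(inc)
    adj <- shared >= (k - 1)
    cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                              diag = FALSE)
    comp <- igraph::components(cg)$membership
    comms <- lapply(split(seq_along(mc), comp), function(ix) {
      sort(unique(unlist(mc[ix])))
    })
    comms <- canonical_setlist(unname(comms))
  }
  membership <- stats::setNames(integer(length(nodes)), nodes)
  for (cm in comms) membership[cm] <- membership[cm] + 1L
  structure(list(k = k, communities = comms, membership = membership,
                 feature_type = types),
            class = "community_set")
}

#' @export
print.community_set <- function(x, ...) {
  sizes <- lengths(x$communities)
  cat(sprintf("<community_set> k = %d: %d communities%s, %d bridge node(s)\n",
              x$k, length(sizes),
              if (length(sizes) > 0) {
                sprintf(" (sizes %s)", paste(sizes, collapse = ", "))
              } else "",
              sum(x$membership >= 2)))
  invisible(x)
}

#' Overlap structure of a community set
#'
#' Bridge nodes (membership >= 2) are, by construction, features tying
#' distinct communities — candidate links between biochemical mechanisms.
#'
#' @param cs A `community_set`.
#' @return A list: `membership_distribution` (histogram of membership counts
#'   over nodes in at least one community), `bridge_nodes` (data frame of
#'   id, omics_type, membership), and `shared` (data frame of community
#'   pairs with their shared-node sets; only pairs sharing nodes).
#' @export
community_overlap <- function(cs) {
  stopifnot(inherits(cs, "community_set"))
  mem <- cs$membership[cs$membership >= 1]
  dist_tab <- table(factor(mem, levels = sort(unique(mem))))
  membership_distribution <- stats::setNames(as.integer(dist_tab),
                                             names(dist_tab))
  bridge_ids <- names(cs$membership)[cs$membership >= 2]
  bridge_nodes <- data.frame(
    id = bridge_ids,
    omics_type = if (!is.null(cs$feature_type)) {
      unname(cs$feature_type[bridge_ids])
    } else {
      rep(NA_character_, length(bridge_ids))
    },
    membership = unname(cs$membership[bridge_ids]),
    stringsAsFactors = FALSE)
  pairs <- list()
  nc <- length(cs$communities)
  if (nc >= 2) {
    for (i in seq_len(nc - 1)) {
      for (j in (i + 1):nc) {
        sh <- intersect(cs$communities[[i]], cs$communities[[j]])
        if (length(sh) > 0) {
          pairs[[length(pairs) + 1]] <- data.frame(
            community_i = i, community_j = j, n_shared = length(sh),
            shared = paste(sh, collapse = ";"), stringsAsFactors = FALSE)
        }
      }
    }
  }
  shared <- if (length(pairs) > 0) {
    do.call(rbind, pairs)
  } else {
    data.frame(community_i = integer(0), community_j = integer(0),
               n_shared = integer(0), shared = character(0),
               stringsAsFactors = FALSE)
  }
  list(membership_distribution = membership_distribution,
       bridge_nodes = bridge_nodes, shared = shared)
}
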
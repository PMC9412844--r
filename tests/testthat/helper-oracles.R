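# Independent brute-force oracles. Each reimplements a quantity from its
# definition, sharing no code path with the package implementation.

# Spearman by explicit rank-then-Pearson
oracle_spearman <- function(v) {
  r <- apply(v, 2, rank, ties.method = "average")
  stats::cor(r, method = "pearson")
}

# all maximal cliques of an adjacency matrix by power-set enumeration
oracle_max_cliques <- function(adj) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  is_clique <- function(ix) {
    if (length(ix) <= 1) return(TRUE)
    all(adj[ix, ix][upper.tri(diag(length(ix)))] == 1)
  }
  cliques <- list()
  for (size in n:1) {
    for (ix in utils::combn(n, size, simplify = FALSE)) {
      if (!is_clique(ix)) next
      covered <- any(vapply(cliques, function(cl) all(ix %in% cl),
                            logical(1)))
      if (!covered) cliques[[length(cliques) + 1]] <- ix
    }
  }
  out <- lapply(cliques, function(ix) sort(nodes[ix]))
  out[order(vapply(out, paste, character(1), collapse = "\r"))]
}

# k-clique communities straight from the definition: enumerate ALL k-cliques,
# link those sharing exactly k-1 nodes, percolate, take node unions
oracle_k_clique_communities <- function(adj, k) {
  n <- nrow(adj)
  nodes <- rownames(adj)
  if (n < k) return(list())
  kcl <- Filter(function(ix) {
    length(ix) == 1 ||
      all(adj[ix, ix][upper.tri(diag(length(ix)))] == 1)
  }, utils::combn(n, k, simplify = FALSE))
  if (length(kcl) == 0) return(list())
  m <- length(kcl)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      if (i < j && length(intersect(kcl[[i]], kcl[[j]])) == k - 1) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  comms <- lapply(split(seq_len(m), roots), function(ix) {
    sort(nodes[unique(unlist(kcl[ix]))])
  })
  comms <- unname(comms)
  comms[order(vapply(comms, paste, character(1), collapse = "\r"))]
}

# topology statistics by direct definition (triangles by triple enumeration)
oracle_topology <- function(adj) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  m <- sum(adj) / 2
  lc <- numeric(n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- which(adj[i, ] == 1)
    tri <- 0
    for (a in seq_along(nb)) {
      for (b in seq_along(nb)) {
        if (a < b && adj[nb[a], nb[b]] == 1) tri <- tri + 1
      }
    }
    lc[i] <- tri / (deg[i] * (deg[i] - 1) / 2)
  }
  # connected components by BFS
  seen <- rep(FALSE, n)
  ncomp <- 0
  for (s in seq_len(n)) {
    if (seen[s]) next
    ncomp <- ncomp + 1
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] == 1)) {
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
  }
  list(n_nodes = n, n_edges = m,
       density = if (n >= 2) m / (n * (n - 1) / 2) else NA_real_,
       avg_degree = mean(deg), avg_clustering = mean(lc),
       n_components = ncomp, n_isolated = sum(deg == 0))
}

# OLS of log10 y on log10 x via explicit normal equations
oracle_loglog_ols <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  n <- length(lx)
  sxx <- sum((lx - mean(lx))^2)
  sxy <- sum((lx - mean(lx)) * (ly - mean(ly)))
  b <- sxy / sxx
  a0 <- mean(ly) - b * mean(lx)
  yhat <- a0 + b * lx
  ss_res <- sum((ly - yhat)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  list(a = 10^a0, b = b, r_squared = 1 - ss_res / ss_tot)
}

# smallest significant Spearman rho by 1e-6 grid scan of the t approximation
oracle_min_sig_threshold <- function(n, alpha = 0.05, step = 1e-6) {
  rho <- seq(step, 1 - step, by = step)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  p <- 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  rho[which(p < alpha)[1]]
}

# minimum no-singleton dendrogram cut by exhaustive search over merge
# heights, clustering leaves by cophenetic-distance components
oracle_min_nosingleton_cut <- function(hc, cap = 0.7) {
  cd <- as.matrix(stats::cophenetic(hc))
  for (h in sort(unique(hc$height))) {
    if (h > cap + 1e-12) break
    g <- igraph::graph_from_adjacency_matrix(cd <= h + 1e-12,
                                             mode = "undirected", diag = FALSE)
    sizes <- igraph::components(g)$csize
    if (min(sizes) >= 2) return(h)
  }
  cap
}

# per-sample cluster medians by sort-and-middle
oracle_pooled_medians <- function(values, clusters) {
  labs <- sort(unique(clusters))
  out <- matrix(NA_real_, nrow(values), length(labs))
  for (ci in seq_along(labs)) {
    cols <- which(clusters == labs[ci])
    for (s in seq_len(nrow(values))) {
      v <- sort(values[s, cols])
      m <- length(v)
      out[s, ci] <- if (m %% 2 == 1) v[(m + 1) / 2] else
        (v[m / 2] + v[m / 2 + 1]) / 2
    }
  }
  out
}

# optimal one-to-one community assignment by permutation enumeration
oracle_best_matching <- function(a, b, min_jaccard = 0.5) {
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(list(pairs = cbind(integer(0), integer(0))))
  k <- min(na, nb)
  best <- NULL; best_score <- -Inf
  idx_a <- utils::combn(na, k, simplify = FALSE)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  }
  idx_b <- perms(seq_len(nb))
  for (ia in idx_a) {
    for (ib in idx_b) {
      ibk <- ib[seq_len(k)]
      js <- mapply(function(i, j) jac(a[[i]], b[[j]]), ia, ibk)
      keep <- js >= min_jaccard
      score <- sum(js[keep])
      if (score > best_score + 1e-12) {
        best_score <- score
        best <- cbind(ia[keep], ibk[keep])
      }
    }
  }
  list(pairs = best, score = best_score)
}

# adjusted Rand index between two labellings
oracle_ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  mx <- (b + cc) / 2
  (a - expected) / (mx - expected)
}

# random G(n, p) adjacency with node names
random_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- stats::rbinom(n * (n - 1) / 2, 1, p)
  adj <- adj + t(adj)
  dimnames(adj) <- list(paste0("n", seq_len(n)), paste0("n", seq_len(n)))
  adj
}

graph_from_adj <- function(adj) {
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

# random feature table fixture
random_table <- function(n_samples = 10, n_features = 5, type = "microbiome",
                         prefix = "f") {
  v <- matrix(stats::rnorm(n_samples * n_features), n_samples, n_features,
              dimnames = list(paste0("s", seq_len(n_samples)),
                              paste0(prefix, seq_len(n_features))))
  feature_table(v, type)
}
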
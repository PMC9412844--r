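# Network summary statistics used to compare groups: density, clustering,
# components, isolated nodes and the log-log power-law fit of the degree
# distribution.

#' Summarise the topology of an omics network
#'
#' Local clustering coefficient is triangles / (deg * (deg - 1) / 2), defined
#' as 0 for degree < 2; the average runs over all nodes. Components are
#' connected components, counting isolated nodes as size-1 components. The
#' degree histogram feeds [fit_power_law()]; the fit is reported when at
#' least 3 distinct positive degrees exist, otherwise it is absent.
#'
#' @param net An `omics_network` (or bare `igraph` graph).
#' @return A `topology_report` list: `n_nodes`, `n_edges`, `density`,
#'   `avg_degree`, `avg_clustering`, `n_components`, `n_isolated`,
#'   `degree_histogram` (named counts) and `powerlaw` (list `a`, `b`,
#'   `r_squared`, `a_probability`, or `NULL`).
#' @export
topology_report <- function(net) {
  g <- if (inherits(net, "omics_network")) net$graph else net
  stopifnot(inherits(g, "igraph"))
  n <- igraph::vcount(g)
  if (n < 1) stop("network must have at least one node", call. = FALSE)
  m <- igraph::ecount(g)
  deg <- igraph::degree(g)
  density <- if (n >= 2) m / (n * (n - 1) / 2) else NA_real_
  lc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  hist_tab <- table(factor(deg, levels = sort(unique(deg))))
  degree_histogram <- stats::setNames(as.integer(hist_tab), names(hist_tab))
  pl <- tryCatch(fit_power_law(degree_histogram),
                 warning = function(w) NULL)
  structure(list(
    n_nodes = n,
    n_edges = m,
    density = density,
    avg_degree = mean(deg),
    avg_clustering = mean(lc),
    n_components = igraph::components(g)$no,
    n_isolated = sum(deg == 0),
    degree_histogram = degree_histogram,
    powerlaw = pl
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "<topology_report> %d nodes, %d edges | density %.3f | avg deg %.2f | avg clust %.3f | %d comp (%d isolated)\n",
    x$n_nodes, x$n_edges, x$density, x$avg_degree, x$avg_clustering,
    x$n_components, x$n_isolated))
  if (!is.null(x$powerlaw)) {
    cat(sprintf("  power-law fit y = a x^b: a = %.3g, b = %.3g, R^2 = %.3f\n",
                x$powerlaw$a, x$powerlaw$b, x$powerlaw$r_squared))
  }
  invisible(x)
}

#' Fit a power law to a degree histogram
#'
#' Ordinary least squares of `log10(count)` on `log10(degree)`, i.e. the
#' straight line a degree distribution traces on log-log axes when it
#' approximates a power law `y = a x^b`. Degree-0 nodes are excluded (log 0
#' undefined) but remain in all other topology statistics. Both the
#' frequency-scaled intercept `a` and the probability-scaled
#' `a_probability = a / sum(count)` are reported, since only the intercept
#' depends on that choice. A complementary-CDF variant is available for
#' diagnostics but the default matches the raw frequency fit.
#'
#' @param degree_histogram Named integer vector, names = degrees, values =
#'   node counts.
#' @param on `"frequency"` (default) fits counts; `"ccdf"` fits the
#'   complementary cumulative distribution.
#' @return A list `a`, `b`, `r_squared`, `a_probability`, or `NULL` (with a
#'   warning) when fewer than 3 usable points exist.
#' @export
fit_power_law <- function(degree_histogram, on = c("frequency", "ccdf")) {
  on <- match.arg(on)
  stopifnot(!is.null(names(degree_histogram)))
  deg <- as.numeric(names(degree_histogram))
  cnt <- as.numeric(degree_histogram)
  use <- deg >= 1 & cnt >= 1
  deg <- deg[use]
  cnt <- cnt[use]
  if (on == "ccdf" && length(deg) > 0) {
    o <- order(deg)
    deg <- deg[o]
    cnt <- rev(cumsum(rev(cnt[o])))
  }
  if (length(deg) < 3) {
    warning("power-law fit needs >= 3 distinct positive degrees; fit absent",
            call. = FALSE)
    return(NULL)
  }
  x <- log10(deg)
  y <- log10(cnt)
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res < 1e-24) else 1 - ss_res / ss_tot
  list(a = 10^unname(co[1]),
       b = unname(co[2]),
       r_squared = r2,
       a_probability = 10^unname(co[1]) / sum(cnt))
}
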
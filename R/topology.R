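# Descriptive topology of SD (or simulated) networks: component spectra,
# log-binned densities, power-law slope fits, giant-component statistics,
# reference random networks, modules and edge classes.

#' Connected-component spectrum
#'
#' Exact decomposition of a simple graph into connected components with
#' per-component node and edge counts; components with `N` nodes and `E`
#' edges are the motifs C(N,E).
#'
#' @param network `sd_network` or igraph.
#' @return list of class `component_spectrum`: `sizes` (per-component node
#'   counts, descending), `edges` (matching edge counts), `membership`
#'   (node -> component id), `mean_edges_by_size` (data.frame `N`,
#'   `mean_E`).
#' @export
component_spectrum <- function(network) {
  g <- .as_igraph(network)
  comp <- igraph::components(g)
  # edge count per component: both endpoints share the membership
  el <- igraph::as_edgelist(g, names = FALSE)
  ecomp <- comp$membership[el[, 1]]
  e_counts <- integer(comp$no)
  if (nrow(el)) {
    tab <- table(ecomp)
    e_counts[as.integer(names(tab))] <- as.integer(tab)
  }
  ord <- order(comp$csize, decreasing = TRUE)
  sizes <- comp$csize[ord]
  edges <- e_counts[ord]
  agg <- stats::aggregate(edges, by = list(N = sizes), FUN = mean)
  names(agg)[2] <- "mean_E"
  structure(list(sizes = as.integer(sizes), edges = as.integer(edges),
                 membership = comp$membership,
                 mean_edges_by_size = agg[order(agg$N), ]),
            class = "component_spectrum")
}

#' Logarithmically binned density
#'
#' Bins positive values into geometrically growing bins and reports the
#' density `n_i / (N * b_i)` per bin, where `n_i` is the count in bin `i`,
#' `N` the total number of observations and `b_i` the bin width. Used to
#' de-noise heavy-tailed distributions on log-log axes.
#'
#' @param values positive observations (component sizes, degrees, ...).
#' @param bins_per_decade number of bins per factor of 10 (default 8).
#' @return data.frame with `lo`, `hi` (bin edges), `center` (geometric
#'   mean), `count`, `density`; empty bins are retained.
#' @export
log_binned_density <- function(values, bins_per_decade = 8) {
  if (any(values <= 0)) stop("values must be positive")
  n_total <- length(values)
  lo <- floor(log10(min(values)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(values)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  edges <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  counts <- as.integer(
    table(cut(values, breaks = edges, include.lowest = TRUE, right = FALSE)))
  # values equal to the top edge fall outside right-open bins; fold back
  counts[length(counts)] <- counts[length(counts)] +
    sum(values >= edges[length(edges)])
  widths <- diff(edges)
  data.frame(lo = edges[-length(edges)], hi = edges[-1],
             center = sqrt(edges[-length(edges)] * edges[-1]),
             count = counts,
             density = counts / (n_total * widths))
}

#' Ordinary least squares on log-log axes
#'
#' @param x,y positive vectors (>= 3 points).
#' @param weights optional regression weights.
#' @return list `slope`, `intercept`, `stderr`.
#' @export
fit_loglog_slope <- function(x, y, weights = NULL) {
  keep <- x > 0 & y > 0
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 positive points")
  if (length(unique(x)) < 2) stop("degenerate x: all values equal")
  fit <- stats::lm(log(y) ~ log(x), weights = weights[keep])
  # summary() warns on numerically perfect fits; stderr 0 is fine here
  cf <- suppressWarnings(summary(fit)$coefficients)
  list(slope = unname(cf[2, 1]), intercept = unname(cf[1, 1]),
       stderr = unname(cf[2, 2]))
}

#' Fit the power-law slope of a component-size spectrum
#'
#' Log-bins the component sizes and regresses log density on log bin
#' center over non-empty bins. The giant component shows up as an isolated
#' peak far right of the power-law bulk; `drop_largest` removes the largest
#' `drop_largest` component(s) before binning so the bulk slope is not
#' polluted by it.
#'
#' @param spectrum `component_spectrum` or an integer vector of sizes.
#' @param bins_per_decade passed to [log_binned_density()].
#' @param drop_largest number of largest components to exclude.
#' @return list `slope`, `intercept`, `stderr`.
#' @export
spectrum_slope <- function(spectrum, bins_per_decade = 8, drop_largest = 0) {
  sizes <- if (inherits(spectrum, "component_spectrum")) spectrum$sizes
           else as.integer(spectrum)
  sizes <- sort(sizes, decreasing = TRUE)
  if (drop_largest > 0) sizes <- sizes[-seq_len(drop_largest)]
  dens <- log_binned_density(sizes, bins_per_decade)
  dens <- dens[dens$count > 0, ]
  fit_loglog_slope(dens$center, dens$density)
}

#' Giant-component clustering and path length
#'
#' The mean clustering coefficient is the unweighted average over all
#' giant-component nodes of the per-node coefficient (edges among
#' neighbours over k(k-1)/2; defined 0 for degree < 2). The average
#' shortest path length is the exact mean over all unordered node pairs
#' within the giant component.
#'
#' @param network `sd_network` or igraph.
#' @return list `clustering`, `path_length`, `n_nodes`, `n_edges`.
#' @export
giant_component_stats <- function(network) {
  g <- .as_igraph(network)
  if (igraph::vcount(g) == 0) stop("empty network")
  comp <- igraph::components(g)
  gc_id <- which.max(comp$csize)
  gc <- igraph::induced_subgraph(g, which(comp$membership == gc_id))
  cc <- igraph::transitivity(gc, type = "localaverage", isolates = "zero")
  # transitivity(localaverage) averages over nodes with degree >= 2 only
  # when isolates drop; with isolates="zero" degree<2 nodes count as 0,
  # matching the convention used here.
  pl <- igraph::mean_distance(gc, directed = FALSE, unconnected = FALSE)
  list(clustering = cc, path_length = pl,
       n_nodes = igraph::vcount(gc), n_edges = igraph::ecount(gc))
}

#' Reference random networks
#'
#' Generators used for comparison with the SD giant component: `er`, an
#' Erdos-Renyi G(n, m) graph with exactly `n` nodes and `m` edges; `ba`, a
#' Barabasi-Albert preferential-attachment graph adding `k` edges per new
#' node; `config`, a configuration-model realisation of a degree sequence
#' with self-loops and multi-edges erased afterwards.
#'
#' @param kind `"er"`, `"ba"` or `"config"`.
#' @param n,m nodes / edges for `er`.
#' @param k edges per new node for `ba` (the SD comparison uses k = 7).
#' @param degrees degree sequence for `config` (sum must be even).
#' @param seed optional RNG seed.
#' @return igraph.
#' @export
reference_network <- function(kind = c("er", "ba", "config"),
                              n = NULL, m = NULL, k = 7, degrees = NULL,
                              seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed)
  if (kind == "er") {
    stopifnot(!is.null(n), !is.null(m))
    igraph::sample_gnm(n, m)
  } else if (kind == "ba") {
    stopifnot(!is.null(n))
    igraph::sample_pa(n, m = k, directed = FALSE)
  } else {
    stopifnot(!is.null(degrees))
    if (sum(degrees) %% 2 != 0) stop("infeasible degree sequence: odd sum")
    g <- igraph::sample_degseq(degrees, method = "configuration")
    igraph::simplify(g)
  }
}

#' Label-propagation modules
#'
#' Asynchronous label propagation until labels are stable under one more
#' sweep; tie-breaking is random, so a seed fixes the partition.
#'
#' @param network `sd_network` or igraph.
#' @param seed RNG seed.
#' @return integer membership vector (node -> module label).
#' @export
detect_modules <- function(network, seed = NULL) {
  g <- .as_igraph(network)
  if (!is.null(seed)) set.seed(seed)
  igraph::membership(igraph::cluster_label_prop(g))
}

#' Intrachromosomal and tandem edge fractions
#'
#' An edge is intrachromosomal if both regions lie on one chromosome, and
#' tandem if additionally the gap between the nearest region boundaries is
#' below `tandem_dist` (5e5 bp by default).
#'
#' @param net `sd_network` with node coordinates.
#' @param tandem_dist tandem distance threshold in bp.
#' @return list `intra_fraction`, `tandem_fraction`.
#' @export
edge_class_fractions <- function(net, tandem_dist = 5e5) {
  stopifnot(inherits(net, "sd_network"))
  if (!all(c("chrom", "start", "end") %in% names(net$nodes)))
    stop("node coordinates missing")
  if (nrow(net$edges) == 0) return(list(intra_fraction = NA_real_,
                                        tandem_fraction = NA_real_))
  nd <- net$nodes
  ia <- match(net$edges$a, nd$region_id)
  ib <- match(net$edges$b, nd$region_id)
  intra <- nd$chrom[ia] == nd$chrom[ib]
  gap <- pmax(pmax(nd$start[ia], nd$start[ib]) -
              pmin(nd$end[ia], nd$end[ib]), 0)
  tandem <- intra & gap < tandem_dist
  list(intra_fraction = mean(intra), tandem_fraction = mean(tandem))
}
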
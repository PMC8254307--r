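# Merging alignment sides into duplicated regions and building the SD
# network. A duplicated region is the maximal union of overlapping
# alignment sides on one chromosome; regions are the network nodes.

#' Merge alignment sides into duplicated regions
#'
#' Every alignment contributes its two sides as genomic intervals. Sides are
#' optionally extended by `padding` bp on both ends (clipped at 0 and, when
#' `chrom_lengths` is given, at the chromosome end), and intervals sharing
#' at least 1 bp are merged transitively into maximal regions. Intervals
#' that merely touch under half-open semantics do not merge. Region bounds
#' are recorded unpadded (the union of the original sides in each padded
#' cluster), so padding perturbs only which sides cluster together, never
#' the recorded region lengths.
#'
#' @param alns `sd_alignments`.
#' @param padding signed padding P in bp; negative P shrinks sides and must
#'   be smaller in magnitude than every side length.
#' @param chrom_lengths optional named vector of chromosome lengths used to
#'   clip padded intervals.
#' @return list with `regions` (data.frame: `region_id`, `chrom`, `start`,
#'   `end`, `length`) and `side_to_region` (integer vector of length
#'   `2 * nrow(alns)`; entries `1..n` are the first sides, `n+1..2n` the
#'   second sides).
#' @export
merge_to_regions <- function(alns, padding = 0, chrom_lengths = NULL) {
  n <- nrow(alns)
  if (n == 0) stop("no alignments to merge")
  chrom <- c(alns$chrom_a, alns$chrom_b)
  start0 <- c(alns$start_a, alns$start_b)   # 0-based half-open
  end0 <- c(alns$end_a, alns$end_b)
  if (padding < 0 && any(end0 - start0 <= -2 * padding))
    stop("negative padding exceeds an alignment-side length")
  ps <- pmax(start0 - padding, 0)
  pe <- end0 + padding
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[chrom]
    pe <- ifelse(is.na(lim), pe, pmin(pe, lim))
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(ps + 1L, pe))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  side_to_region <- integer(2L * n)
  reg_chrom <- as.character(GenomicRanges::seqnames(red))
  reg_start <- integer(length(red))
  reg_end <- integer(length(red))
  for (i in seq_along(red)) {
    sides <- revmap[[i]]
    side_to_region[sides] <- i
    reg_start[i] <- min(start0[sides])   # unpadded union bounds
    reg_end[i] <- max(end0[sides])
  }
  ord <- order(reg_chrom, reg_start)
  rank <- match(seq_along(red), ord)
  regions <- data.frame(region_id = seq_along(red),
                        chrom = reg_chrom[ord],
                        start = reg_start[ord],
                        end = reg_end[ord],
                        stringsAsFactors = FALSE)
  regions$length <- regions$end - regions$start
  list(regions = regions, side_to_region = rank[side_to_region])
}

#' Build the SD network from regions and alignments
#'
#' Each alignment joins the two regions containing its sides. Alignments
#' whose sides fall into the same region are recorded as self-loops; pairs
#' of distinct regions joined by several alignments carry a multiplicity.
#' The trimmed view (the `graph` element, an igraph object) drops
#' self-loops and collapses multiplicities to simple edges; the untrimmed
#' multiplicities and self-loop counts are kept alongside.
#'
#' @param regions,side_to_region output of [merge_to_regions()].
#' @param alns the `sd_alignments` the regions were built from.
#' @return an object of class `sd_network`: list with `nodes` (region table
#'   with `degree`), `edges` (`a`, `b`, `multiplicity`), `self_loops`
#'   (named integer vector), and `graph` (trimmed simple igraph).
#' @export
build_network <- function(regions, side_to_region, alns) {
  n <- nrow(alns)
  if (length(side_to_region) != 2L * n || any(side_to_region == 0))
    stop("every alignment side must be mapped to a region")
  ra <- side_to_region[seq_len(n)]
  rb <- side_to_region[n + seq_len(n)]
  loops <- ra == rb
  self_loops <- table(ra[loops])
  self_loops <- setNames(as.integer(self_loops), names(self_loops))
  a <- pmin(ra[!loops], rb[!loops])
  b <- pmax(ra[!loops], rb[!loops])
  if (length(a)) {
    key <- paste(a, b)
    mult <- table(key)
    uk <- strsplit(names(mult), " ")
    edges <- data.frame(a = as.integer(vapply(uk, `[`, "", 1)),
                        b = as.integer(vapply(uk, `[`, "", 2)),
                        multiplicity = as.integer(mult))
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(a = integer(), b = integer(),
                        multiplicity = integer())
  }
  g <- igraph::make_empty_graph(n = nrow(regions), directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  nodes <- regions
  nodes$degree <- igraph::degree(g)
  structure(list(nodes = nodes, edges = edges, self_loops = self_loops,
                 graph = g),
            class = "sd_network")
}

#' @export
print.sd_network <- function(x, ...) {
  cat("SD network:", nrow(x$nodes), "nodes,",
      igraph::ecount(x$graph), "edges (trimmed);",
      sum(x$edges$multiplicity) + sum(x$self_loops),
      "supporting alignments,", sum(x$self_loops), "self-loop(s)\n")
  invisible(x)
}

#' One-call network construction from an alignment table
#'
#' Convenience wrapper: filter, merge, build.
#'
#' @inheritParams filter_alignments
#' @inheritParams merge_to_regions
#' @return `sd_network`.
#' @export
sd_network_from_alignments <- function(alns, min_len = 1000,
                                       min_identity = 0.90,
                                       autosomes_only = TRUE,
                                       exclude_mask = NULL, padding = 0,
                                       chrom_lengths = NULL) {
  alns <- filter_alignments(alns, min_len, min_identity, autosomes_only,
                            exclude_mask)
  m <- merge_to_regions(alns, padding, chrom_lengths)
  build_network(m$regions, m$side_to_region, alns)
}

# Coerce sd_network / igraph to igraph
.as_igraph <- function(x) {
  if (igraph::is_igraph(x)) return(x)
  if (inherits(x, "sd_network")) return(x$graph)
  stop("expected an igraph or sd_network object")
}

#' Write an SD network to a directory
#'
#' Writes `nodes.tsv` (region id, coordinates, length, degree), `edges.tsv`
#' (region pair + multiplicity), `self_loops.tsv`, and `regions.bed`
#' (BED4). [read_sd_network()] round-trips the result.
#'
#' @param net `sd_network`.
#' @param dir output directory (created if needed).
#' @export
write_sd_network <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(net$nodes, file.path(dir, "nodes.tsv"), sep = "\t")
  data.table::fwrite(net$edges, file.path(dir, "edges.tsv"), sep = "\t")
  sl <- data.frame(region_id = as.integer(names(net$self_loops)),
                   count = as.integer(net$self_loops))
  data.table::fwrite(sl, file.path(dir, "self_loops.tsv"), sep = "\t")
  bed <- net$nodes[, c("chrom", "start", "end", "region_id")]
  data.table::fwrite(bed, file.path(dir, "regions.bed"), sep = "\t",
                     col.names = FALSE)
  invisible(dir)
}

#' Read an SD network written by [write_sd_network()]
#'
#' @param dir directory.
#' @return `sd_network`.
#' @export
read_sd_network <- function(dir) {
  nodes <- data.table::fread(file.path(dir, "nodes.tsv"),
                             data.table = FALSE)
  edges <- data.table::fread(file.path(dir, "edges.tsv"),
                             data.table = FALSE)
  sl <- data.table::fread(file.path(dir, "self_loops.tsv"),
                          data.table = FALSE)
  g <- igraph::make_empty_graph(n = nrow(nodes), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  structure(list(nodes = nodes, edges = edges,
                 self_loops = setNames(as.integer(sl$count),
                                       as.character(sl$region_id)),
                 graph = g),
            class = "sd_network")
}
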
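# Shared fixtures and independent oracles for the test suite.

# Random alignment table on a toy two-chromosome genome.
random_alignments <- function(n, chrom_len = 1e5, max_len = 5e3,
                              chroms = c("chr1", "chr2")) {
  len <- sample(500:max_len, n, replace = TRUE)
  ca <- sample(chroms, n, replace = TRUE)
  cb <- sample(chroms, n, replace = TRUE)
  sa <- sapply(len, function(l) sample.int(chrom_len - l, 1))
  sb <- sapply(len, function(l) sample.int(chrom_len - l, 1))
  sd_alignments(ca, sa, sa + len, cb, sb, sb + len,
                identity = runif(n, 0.9, 1), aln_length = len)
}

# Brute-force O(n^2) pairwise-overlap closure: the independent oracle for
# merge_to_regions. Intervals sharing >= 1 bp (half-open) are clustered
# transitively; returns the sorted unpadded union bounds per cluster.
brute_force_regions <- function(chrom, start, end, padding = 0) {
  n <- length(start)
  ps <- pmax(start - padding, 0)
  pe <- end + padding
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (chrom[i] == chrom[j] && ps[i] < pe[j] && ps[j] < pe[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  root <- vapply(seq_len(n), find, 1L)
  out <- do.call(rbind, lapply(split(seq_len(n), root), function(idx) {
    data.frame(chrom = chrom[idx[1]], start = min(start[idx]),
               end = max(end[idx]), stringsAsFactors = FALSE)
  }))
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}

# Small sd_network built by hand from explicit node/edge tables (for
# topology and feature tests that need full control).
manual_network <- function(nodes, edges,
                           self_loops = integer(0)) {
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  nodes$degree <- igraph::degree(g)
  if (is.null(nodes$length)) nodes$length <- nodes$end - nodes$start
  structure(list(nodes = nodes, edges = edges, self_loops = self_loops,
                 graph = g),
            class = "sd_network")
}
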
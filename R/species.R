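# Cross-species comparison of SD networks through their component-size
# spectra: pairwise Bray-Curtis dissimilarity and hierarchical clustering.

#' Pairwise spectrum dissimilarity matrix
#'
#' Bray-Curtis dissimilarity between the sorted-descending top-`top_n`
#' component-size vectors (zero-padded to equal length) of each species.
#'
#' @param spectra named list: species -> integer component-size vector.
#' @param top_n vector length (paper convention: 500).
#' @return symmetric matrix with zero diagonal, entries in \[0, 1\].
#' @export
spectrum_dissimilarity_matrix <- function(spectra, top_n = 500) {
  if (length(spectra) < 2) stop("need at least 2 species")
  if (any(vapply(spectra, length, 1L) == 0)) stop("empty spectrum")
  vecs <- vapply(spectra, top_sizes, numeric(top_n), top_n = top_n)
  k <- length(spectra)
  m <- matrix(0, k, k, dimnames = list(names(spectra), names(spectra)))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- bray_curtis(vecs[, i], vecs[, j])
  }
  m
}

#' Hierarchical clustering of species spectra
#'
#' Agglomerative clustering of the dissimilarity matrix (average linkage /
#' UPGMA by default), with Newick export of the dendrogram.
#'
#' @param dissim dissimilarity matrix from
#'   [spectrum_dissimilarity_matrix()].
#' @param linkage `"average"`, `"complete"` or `"single"`.
#' @param newick_file optional path; when given the tree is written in
#'   Newick format.
#' @return list `hclust`, `phylo` (ape tree), `order` (leaf order),
#'   `similarity` (1 - dissimilarity, ordered by leaves for heatmaps).
#' @export
cluster_species <- function(dissim, linkage = c("average", "complete",
                                                "single"),
                            newick_file = NULL) {
  linkage <- match.arg(linkage)
  stopifnot(isSymmetric(unname(dissim)), all(diag(dissim) == 0))
  hc <- stats::hclust(stats::as.dist(dissim), method = linkage)
  phy <- ape::as.phylo(hc)
  if (!is.null(newick_file)) ape::write.tree(phy, file = newick_file)
  ord <- hc$labels[hc$order]
  list(hclust = hc, phylo = phy, order = ord,
       similarity = (1 - dissim)[ord, ord])
}
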
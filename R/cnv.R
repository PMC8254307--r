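# CNV fixation analysis: how the population frequency spectrum of copy
# number variants depends on the node degree of the duplicated region they
# overlap.

CNV_CLASS_BREAKS <- list(rare = c(1, 3), medium = c(4, 15),
                         high = c(16, 2504))
DEGREE_BIN_BREAKS <- list(`[1,1]` = c(1, 1), `[2,5]` = c(2, 5),
                          `[6,30]` = c(6, 30), `[31,140]` = c(31, 140))

#' Classify a CNV by minor allele count
#'
#' Rare: MAC in \[1, 3\]; medium: \[4, 15\]; high: \[16, 2504\]
#' (cohort of 2504 diploid individuals).
#'
#' @param mac integer MAC vector (>= 1).
#' @return factor with levels `rare`, `medium`, `high`.
#' @export
classify_cnv <- function(mac) {
  stopifnot(all(mac >= 1))
  if (any(mac > 2504)) stop("MAC exceeds the cohort bound of 2504")
  cut(mac, breaks = c(0, 3, 15, 2504),
      labels = c("rare", "medium", "high"))
}

#' Classify a duplicated region by node degree
#'
#' Bins: \[1, 1\], \[2, 5\], \[6, 30\], \[31, 140\]. Degrees above 140
#' (the largest observed in the human SD network) are assigned to the top
#' bin with a warning.
#'
#' @param degree integer node degrees (>= 1).
#' @return factor with the four bin labels.
#' @export
classify_region <- function(degree) {
  stopifnot(all(degree >= 1))
  if (any(degree > 140)) {
    warning("degree > 140 assigned to the top bin")
    degree <- pmin(degree, 140)
  }
  cut(degree, breaks = c(0, 1, 5, 30, 140),
      labels = names(DEGREE_BIN_BREAKS))
}

#' CNV frequency-class fractions by region degree class
#'
#' For every region degree bin, collects the CNVs overlapping (>= 1 bp) at
#' least one region of that bin (each CNV counted once per bin but allowed
#' in several bins) and tabulates the fraction of rare / medium / high
#' frequency CNVs. The `not_duplicated` row collects CNVs overlapping no
#' duplicated region at all.
#'
#' @param regions data.frame with `chrom`, `start`, `end`, `degree`
#'   (e.g. the `nodes` table of an [build_network()] result).
#' @param cnvs data.frame with `chrom`, `start`, `end`, `mac`
#'   (see [read_cnvs()]).
#' @return data.frame with one row per region class: `region_class`, `n`
#'   (overlapping CNVs), `rare`, `medium`, `high` fractions (NA when no
#'   CNV overlaps the class).
#' @export
overlap_fraction_table <- function(regions, cnvs) {
  if (nrow(cnvs) == 0) stop("empty CNV set")
  regions <- regions[regions$degree >= 1, , drop = FALSE]
  cnv_gr <- GenomicRanges::GRanges(
    cnvs$chrom, IRanges::IRanges(cnvs$start + 1L, cnvs$end))
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  reg_class <- classify_region(regions$degree)
  cnv_class <- classify_cnv(cnvs$mac)
  hits <- GenomicRanges::findOverlaps(cnv_gr, reg_gr)
  hit_bin <- reg_class[S4Vectors::subjectHits(hits)]
  hit_cnv <- S4Vectors::queryHits(hits)
  classes <- c(names(DEGREE_BIN_BREAKS), "not_duplicated")
  rows <- lapply(classes, function(cl) {
    idx <- if (cl == "not_duplicated") {
      setdiff(seq_len(nrow(cnvs)), unique(hit_cnv))
    } else {
      unique(hit_cnv[hit_bin == cl])
    }
    if (!length(idx))
      return(data.frame(region_class = cl, n = 0L, rare = NA_real_,
                        medium = NA_real_, high = NA_real_))
    tab <- table(cnv_class[idx]) / length(idx)
    data.frame(region_class = cl, n = length(idx),
               rare = as.numeric(tab["rare"]),
               medium = as.numeric(tab["medium"]),
               high = as.numeric(tab["high"]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
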
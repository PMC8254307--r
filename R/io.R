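#' @importFrom data.table fread fwrite data.table :=
#' @importFrom stats setNames
NULL

.datatable.aware <- TRUE

# Canonical chromosome label handling -----------------------------------

AUTOSOME_LABELS <- c(paste0("chr", 1:22), as.character(1:22))
SEX_LABELS <- c("chrX", "chrY", "X", "Y")

#' Is a chromosome label an autosome?
#'
#' Accepts both UCSC-style (`chr1`..`chr22`) and bare (`1`..`22`) labels.
#'
#' @param chrom character vector of chromosome labels.
#' @return logical vector.
#' @export
is_autosome <- function(chrom) chrom %in% AUTOSOME_LABELS

.is_known_chrom <- function(chrom) {
  chrom %in% c(AUTOSOME_LABELS, SEX_LABELS, "chrM", "MT", "M")
}

# SD alignment tables ----------------------------------------------------

.aln_cols <- c("chrom_a", "start_a", "end_a",
               "chrom_b", "start_b", "end_b",
               "identity", "aln_length")

.validate_alignments <- function(df) {
  stopifnot(all(.aln_cols %in% names(df)))
  ok <- df$start_a < df$end_a & df$start_b < df$end_b &
    df$aln_length >= 1 & df$identity >= 0 & df$identity <= 1
  if (!all(ok)) stop("invalid alignment record(s) at row(s): ",
                     paste(utils::head(which(!ok), 5), collapse = ", "))
  df
}

#' Construct an SD alignment table
#'
#' One row per pairwise local alignment between two genomic intervals.
#' Coordinates are 0-based half-open throughout the package; `identity` is a
#' fraction in \[0, 1\].
#'
#' @param chrom_a,start_a,end_a first alignment side.
#' @param chrom_b,start_b,end_b second alignment side.
#' @param identity alignment identity fraction.
#' @param aln_length alignment length in bp; defaults to the length of the
#'   first side.
#' @return a `data.frame` with class `sd_alignments`.
#' @export
sd_alignments <- function(chrom_a, start_a, end_a,
                          chrom_b, start_b, end_b,
                          identity = 1, aln_length = NULL) {
  if (is.null(aln_length)) aln_length <- end_a - start_a
  df <- data.frame(chrom_a = as.character(chrom_a),
                   start_a = as.integer(start_a), end_a = as.integer(end_a),
                   chrom_b = as.character(chrom_b),
                   start_b = as.integer(start_b), end_b = as.integer(end_b),
                   identity = as.numeric(identity),
                   aln_length = as.numeric(aln_length),
                   stringsAsFactors = FALSE)
  df <- .validate_alignments(df)
  class(df) <- c("sd_alignments", "data.frame")
  df
}

# Positional layout of the UCSC genomicSuperDups track (no-header dumps).
.UCSC_SUPERDUPS_COLS <- c(
  "bin", "chrom", "chromStart", "chromEnd", "name", "score", "strand",
  "otherChrom", "otherStart", "otherEnd", "otherSize", "uid",
  "posBasesHit", "testResult", "verdict", "chits", "ccov", "alignfile",
  "alignL", "indelN", "indelS", "alignB", "matchB", "mismatchB",
  "transitionsB", "transversionsB", "fracMatch", "fracMatchIndel",
  "jcK", "k2K")

# SEDEF-style headerless layout used by write_sd_table() and accepted on
# read; a leading '#' header naming fracMatch overrides positions.
.SEDEF_COLS <- c("chr1", "start1", "end1", "chr2", "start2", "end2",
                 "name", "score", "strand1", "strand2",
                 "max_len", "aln_len", "fracMatch")

#' Read a table of pairwise SD alignments
#'
#' Supported dialects:
#' \describe{
#'   \item{`ucsc`}{UCSC `genomicSuperDups` dump, with or without a header
#'     line; coordinates 0-based half-open, identity in `fracMatch`.}
#'   \item{`sedef`}{SEDEF-style BEDPE output; a `#`-prefixed header naming
#'     `fracMatch` (or `identity`) is honoured, otherwise the 13-column
#'     layout written by [write_sd_table()] is assumed.}
#'   \item{`bedpe`}{plain BEDPE: six interval columns, a name column, and
#'     identity in column 8.}
#' }
#' Identity values greater than 1 are interpreted as percentages. Rows on
#' unrecognised chromosome labels (alt contigs, unplaced scaffolds) and
#' malformed rows are skipped with a warning, or raise an error when
#' `strict = TRUE`.
#'
#' @param path file path.
#' @param dialect one of `"ucsc"`, `"sedef"`, `"bedpe"`.
#' @param strict error on malformed/unknown rows instead of skipping.
#' @return an `sd_alignments` data.frame.
#' @export
read_sd_alignments <- function(path, dialect = c("ucsc", "sedef", "bedpe"),
                               strict = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  # a header names coordinate columns; a data line has bare coordinates
  has_header <- grepl("chromstart|\\bstart1\\b|fracmatch|identity", first,
                      ignore.case = TRUE)
  raw <- fread(path, header = has_header && !startsWith(first, "#"),
               sep = "\t", fill = TRUE, data.table = TRUE,
               colClasses = "character")
  if (startsWith(first, "#")) {
    hdr <- strsplit(sub("^#", "", first), "\t")[[1]]
    if (length(hdr) == ncol(raw)) names(raw) <- hdr
    raw <- raw[-1]
  }
  if (dialect == "ucsc") {
    if (!"chrom" %in% names(raw)) {
      if (ncol(raw) < 27) stop("ucsc dialect expects >= 27 columns")
      k <- min(ncol(raw), length(.UCSC_SUPERDUPS_COLS))
      names(raw)[1:k] <- .UCSC_SUPERDUPS_COLS[1:k]
    }
    cols <- c("chrom", "chromStart", "chromEnd",
              "otherChrom", "otherStart", "otherEnd", "fracMatch")
  } else if (dialect == "sedef") {
    if (!any(c("fracMatch", "identity") %in% names(raw))) {
      if (ncol(raw) < 13) stop("sedef dialect expects >= 13 columns")
      names(raw)[1:13] <- .SEDEF_COLS
    }
    idcol <- intersect(c("fracMatch", "identity"), names(raw))[1]
    cols <- c("chr1", "start1", "end1", "chr2", "start2", "end2", idcol)
  } else {
    if (ncol(raw) < 8) stop("bedpe dialect expects >= 8 columns")
    names(raw)[1:8] <- c("chr1", "start1", "end1", "chr2", "start2", "end2",
                         "name", "identity")
    cols <- c("chr1", "start1", "end1", "chr2", "start2", "end2", "identity")
  }
  missing <- setdiff(cols, names(raw))
  if (length(missing)) stop("missing column(s): ", paste(missing, collapse = ", "))
  sub <- raw[, cols, with = FALSE]
  names(sub) <- c("chrom_a", "start_a", "end_a",
                  "chrom_b", "start_b", "end_b", "identity")
  for (cc in c("start_a", "end_a", "start_b", "end_b", "identity"))
    sub[[cc]] <- suppressWarnings(as.numeric(sub[[cc]]))
  ident <- sub$identity
  ident[!is.na(ident) & ident > 1] <- ident[!is.na(ident) & ident > 1] / 100
  sub$identity <- ident
  bad <- !stats::complete.cases(sub) |
    sub$start_a >= sub$end_a | sub$start_b >= sub$end_b |
    sub$identity < 0 | sub$identity > 1
  unknown <- !.is_known_chrom(sub$chrom_a) | !.is_known_chrom(sub$chrom_b)
  drop <- bad | (unknown & !bad)
  if (any(drop)) {
    msg <- sprintf("%d malformed and %d unknown-chromosome row(s) at line(s) %s",
                   sum(bad), sum(unknown & !bad),
                   paste(utils::head(which(drop), 5), collapse = ", "))
    if (strict) stop(msg) else warning(msg, "; skipped")
    sub <- sub[!drop]
  }
  sd_alignments(sub$chrom_a, sub$start_a, sub$end_a,
                sub$chrom_b, sub$start_b, sub$end_b,
                identity = sub$identity,
                aln_length = sub$end_a - sub$start_a)
}

#' Write an SD alignment table in the SEDEF-style dialect
#'
#' @param alns an `sd_alignments` data.frame.
#' @param path output file.
#' @export
write_sd_table <- function(alns, path) {
  out <- data.table(
    chr1 = alns$chrom_a, start1 = as.integer(alns$start_a),
    end1 = as.integer(alns$end_a),
    chr2 = alns$chrom_b, start2 = as.integer(alns$start_b),
    end2 = as.integer(alns$end_b),
    name = sprintf("SD%06d", seq_len(nrow(alns))), score = 0L,
    strand1 = "+", strand2 = "+",
    max_len = as.integer(pmax(alns$end_a - alns$start_a,
                              alns$end_b - alns$start_b)),
    aln_len = as.integer(alns$aln_length),
    fracMatch = alns$identity)
  writeLines(paste0("#", paste(names(out), collapse = "\t")), path)
  fwrite(out, path, sep = "\t", append = TRUE, col.names = FALSE)
  invisible(path)
}

#' Filter SD alignments by length, identity, chromosome class and mask
#'
#' Default cut-offs follow the conventional SD definition: alignments of at
#' least 1 kbp with at least 90% identity, autosomes only. An optional BED
#' mask (e.g. pericentromeric regions) removes any alignment with either
#' side overlapping the mask by >= 1 bp.
#'
#' @param alns `sd_alignments`.
#' @param min_len minimum alignment length (bp).
#' @param min_identity minimum identity fraction.
#' @param autosomes_only keep only alignments with both sides autosomal.
#' @param exclude_mask optional BED data.frame (`chrom`, `start`, `end`).
#' @return filtered `sd_alignments`.
#' @export
filter_alignments <- function(alns, min_len = 1000, min_identity = 0.90,
                              autosomes_only = TRUE, exclude_mask = NULL) {
  stopifnot(min_len >= 0, min_identity >= 0)
  keep <- alns$aln_length >= min_len & alns$identity >= min_identity
  if (autosomes_only)
    keep <- keep & is_autosome(alns$chrom_a) & is_autosome(alns$chrom_b)
  if (!is.null(exclude_mask) && nrow(alns)) {
    mask_gr <- GenomicRanges::GRanges(
      exclude_mask$chrom,
      IRanges::IRanges(exclude_mask$start + 1L, exclude_mask$end))
    # chromosomes absent from the mask trigger a seqlevel warning only
    hit_a <- suppressWarnings(GenomicRanges::countOverlaps(
      .side_granges(alns, "a"), mask_gr)) > 0
    hit_b <- suppressWarnings(GenomicRanges::countOverlaps(
      .side_granges(alns, "b"), mask_gr)) > 0
    keep <- keep & !hit_a & !hit_b
  }
  out <- alns[keep, , drop = FALSE]
  class(out) <- c("sd_alignments", "data.frame")
  out
}

# GRanges for one side of every alignment (1-based closed internally).
.side_granges <- function(alns, side = c("a", "b")) {
  side <- match.arg(side)
  GenomicRanges::GRanges(
    alns[[paste0("chrom_", side)]],
    IRanges::IRanges(alns[[paste0("start_", side)]] + 1L,
                     alns[[paste0("end_", side)]]))
}

# BED and CNV tables -----------------------------------------------------

#' Read a BED3(+) file
#'
#' @param path file path.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  df <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  df
}

#' Read CNV calls with minor allele counts
#'
#' Two dialects: a 4-column `bed_mac` table (`chrom start end mac`,
#' 0-based half-open) or a structural-variant VCF with per-sample genotypes.
#' For VCF input the minor allele count (MAC) of a record is computed from
#' the called genotypes: the number of non-reference allele occurrences
#' `c` over all samples, folded as `min(c, 2*n_samples - c)`. Records with
#' MAC 0 (monomorphic) and non-autosomal records are dropped.
#'
#' @param path file path.
#' @param dialect `"bed_mac"` or `"vcf"`.
#' @return data.frame with `chrom`, `start`, `end`, `mac`.
#' @export
read_cnvs <- function(path, dialect = c("bed_mac", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "bed_mac") {
    df <- fread(path, header = FALSE, sep = "\t", data.table = FALSE)
    if (ncol(df) < 4) stop("bed_mac dialect expects 4 columns")
    names(df)[1:4] <- c("chrom", "start", "end", "mac")
  } else {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
    gt <- vcfR::extract.gt(vcf, element = "GT")
    if (is.null(gt)) stop("VCF has no genotype (GT) field")
    n_samples <- ncol(gt)
    alt_counts <- apply(gt, 1, function(g) {
      alleles <- unlist(strsplit(g[!is.na(g)], "[/|]"))
      sum(alleles != "0" & alleles != ".")
    })
    pos <- as.integer(fix$POS)
    info <- vcfR::extract.info(vcf, element = "END")
    end <- suppressWarnings(as.integer(info))
    svlen <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "SVLEN")))
    end[is.na(end)] <- pos[is.na(end)] + abs(svlen[is.na(end)])
    end[is.na(end)] <- pos[is.na(end)] + 1L
    mac <- pmin(alt_counts, 2L * n_samples - alt_counts)
    df <- data.frame(chrom = fix$CHROM, start = pos - 1L, end = end,
                     mac = as.integer(mac), stringsAsFactors = FALSE)
    df <- df[df$mac >= 1, , drop = FALSE]
  }
  df <- df[is_autosome(df$chrom), , drop = FALSE]
  if (any(df$start >= df$end)) stop("CNV record with start >= end")
  if (any(df$mac < 1)) stop("CNV record with MAC < 1")
  rownames(df) <- NULL
  df
}
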
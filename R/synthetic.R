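# Synthetic duplication histories: a linear multi-chromosome genome
# accumulates copy-paste events on a static coordinate frame (new copies
# are written into previously empty loci, so coordinates never shift).
# Each event emits the primary alignment (source <-> copy) plus all
# secondary alignments implied by the source overlapping previously
# duplicated sequence; per-base ancestry is tracked exactly, providing an
# independent ground-truth oracle for the network-construction pipeline.

# Secondary alignments for one event: compose the source/dest map through
# every existing alignment (both orientations) where the source overlaps
# an alignment side by at least min_len.
.emit_secondary <- function(alns, src, dest, min_len) {
  if (is.null(alns) || nrow(alns) == 0) return(NULL)
  both <- rbind(
    data.frame(p_chrom = alns$chrom_a, p_start = alns$start_a,
               p_end = alns$end_a, q_chrom = alns$chrom_b,
               q_start = alns$start_b, stringsAsFactors = FALSE),
    data.frame(p_chrom = alns$chrom_b, p_start = alns$start_b,
               p_end = alns$end_b, q_chrom = alns$chrom_a,
               q_start = alns$start_a, stringsAsFactors = FALSE))
  ov_s <- pmax(both$p_start, src$start)
  ov_e <- pmin(both$p_end, src$end)
  hit <- both$p_chrom == src$chrom & (ov_e - ov_s) >= min_len
  if (!any(hit)) return(NULL)
  both <- both[hit, ]; ov_s <- ov_s[hit]; ov_e <- ov_e[hit]
  w <- ov_e - ov_s
  data.frame(
    chrom_a = dest$chrom,
    start_a = dest$start + (ov_s - src$start),
    end_a = dest$start + (ov_s - src$start) + w,
    chrom_b = both$q_chrom,
    start_b = both$q_start + (ov_s - both$p_start),
    end_b = both$q_start + (ov_s - both$p_start) + w,
    stringsAsFactors = FALSE)
}

#' Replay a prescribed list of duplication events
#'
#' Runs the alignment-emission and ancestry bookkeeping for events given
#' explicitly (source interval and insertion locus per event); used both
#' by [simulate_duplication_history()] and to construct hand-designed
#' scenarios in tests.
#'
#' @param events data.frame with columns `src_chrom`, `src_start`,
#'   `src_end`, `dest_chrom`, `dest_start` (0-based half-open).
#' @param n_chroms,chrom_len genome shape.
#' @param min_len minimum overlap for a (secondary) alignment to be
#'   emitted, bp.
#' @param identity_decay identity drop per unit of relative age; the
#'   alignment emitted at event e of n gets identity
#'   `1 - identity_decay * (n - e) / n`.
#' @return object of class `sd_history`: `events`, `alignments`
#'   (`sd_alignments` with an `event` column), `anc` (per-chromosome
#'   integer ancestry vectors), `n_chroms`, `chrom_len`, `min_len`.
#' @export
replay_duplication_events <- function(events, n_chroms, chrom_len,
                                      min_len = 1000,
                                      identity_decay = 0.08) {
  chroms <- paste0("chr", seq_len(n_chroms))
  anc <- lapply(seq_len(n_chroms) - 1L,
                function(i) seq_len(chrom_len) + i * chrom_len)
  names(anc) <- chroms
  alns <- NULL
  n_ev <- nrow(events)
  for (e in seq_len(n_ev)) {
    ev <- events[e, ]
    src <- list(chrom = ev$src_chrom, start = ev$src_start,
                end = ev$src_end)
    dest <- list(chrom = ev$dest_chrom, start = ev$dest_start,
                 end = ev$dest_start + (ev$src_end - ev$src_start))
    primary <- data.frame(chrom_a = src$chrom, start_a = src$start,
                          end_a = src$end, chrom_b = dest$chrom,
                          start_b = dest$start, end_b = dest$end,
                          stringsAsFactors = FALSE)
    secondary <- .emit_secondary(alns, src, dest, min_len)
    new <- rbind(primary, secondary)
    new$identity <- NA_real_
    new$aln_length <- new$end_a - new$start_a
    new$event <- e
    alns <- rbind(alns, new)
    # ancestry: the copy inherits the source's current ancestry
    anc[[dest$chrom]][(dest$start + 1):dest$end] <-
      anc[[src$chrom]][(src$start + 1):src$end]
  }
  alns$identity <- 1 - identity_decay * (n_ev - alns$event) / n_ev
  out <- sd_alignments(alns$chrom_a, alns$start_a, alns$end_a,
                       alns$chrom_b, alns$start_b, alns$end_b,
                       identity = alns$identity,
                       aln_length = alns$aln_length)
  out$event <- alns$event
  structure(list(events = events, alignments = out, anc = anc,
                 n_chroms = n_chroms, chrom_len = chrom_len,
                 min_len = min_len),
            class = "sd_history")
}

#' Simulate a random duplication history
#'
#' At every step a source interval is chosen (uniformly over the genome,
#' or — in preferential mode with probability `pref_weight` — anchored
#' inside a uniformly chosen previously recorded alignment side, which
#' makes highly copied regions proportionally more likely sources, the
#' genomic analogue of the PCM) and pasted into a random empty locus
#' (disjoint from all recorded alignment sides and from the source).
#' Segment lengths are log-uniform on `len_range`.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len chromosome length (bp).
#' @param n_events number of duplication events (>= 1).
#' @param source_mode `"uniform"` or `"preferential"`.
#' @param pref_weight probability that a preferential-mode event anchors
#'   its source in already-duplicated sequence.
#' @param len_range segment-length range, bp (log-uniform draw).
#' @param min_len alignment emission threshold, bp.
#' @param identity_decay see [replay_duplication_events()].
#' @param seed RNG seed.
#' @return `sd_history` (see [replay_duplication_events()]).
#' @export
simulate_duplication_history <- function(n_chroms = 2, chrom_len = 2e5,
                                         n_events = 20,
                                         source_mode = c("uniform",
                                                         "preferential"),
                                         pref_weight = 0.8,
                                         len_range = c(1e3, 1e4),
                                         min_len = 1000,
                                         identity_decay = 0.08,
                                         seed = NULL) {
  source_mode <- match.arg(source_mode)
  stopifnot(n_events >= 1, len_range[1] >= min_len)
  if (!is.null(seed)) set.seed(seed)
  chroms <- paste0("chr", seq_len(n_chroms))
  # occupied intervals (recorded alignment sides) per chromosome
  occ <- stats::setNames(
    replicate(n_chroms, cbind(start = numeric(0), end = numeric(0)),
              simplify = FALSE), chroms)
  sides <- NULL   # all recorded duplicated intervals, for pref. anchoring
  events <- NULL
  for (e in seq_len(n_events)) {
    len <- round(exp(stats::runif(1, log(len_range[1]),
                                  log(len_range[2]))))
    # --- source
    src <- NULL
    if (source_mode == "preferential" && !is.null(sides) &&
        stats::runif(1) < pref_weight) {
      j <- sample.int(nrow(sides), 1)
      anchor <- sides$start[j] +
        floor(stats::runif(1) * (sides$end[j] - sides$start[j]))
      s0 <- max(0, min(anchor - len %/% 2, chrom_len - len))
      src <- list(chrom = sides$chrom[j], start = s0, end = s0 + len)
    }
    if (is.null(src)) {
      ch <- chroms[sample.int(n_chroms, 1)]
      s0 <- floor(stats::runif(1) * (chrom_len - len + 1))
      src <- list(chrom = ch, start = s0, end = s0 + len)
    }
    # --- destination: uniform over empty gaps of sufficient width,
    # avoiding occupied intervals and the source itself
    cand <- list()
    for (ch in chroms) {
      iv <- occ[[ch]]
      if (ch == src$chrom)
        iv <- rbind(iv, c(src$start, src$end))
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      gs <- 0
      gaps <- NULL
      for (r in seq_len(nrow(iv))) {
        if (iv[r, 1] > gs) gaps <- rbind(gaps, c(gs, iv[r, 1]))
        gs <- max(gs, iv[r, 2])
      }
      if (gs < chrom_len) gaps <- rbind(gaps, c(gs, chrom_len))
      if (!is.null(gaps)) {
        ok <- gaps[, 2] - gaps[, 1] >= len
        if (any(ok))
          cand[[ch]] <- cbind(gaps[ok, , drop = FALSE])
      }
    }
    if (!length(cand)) stop("genome exhausted: no empty locus of ", len,
                            " bp at event ", e)
    weights <- unlist(lapply(cand, function(g) g[, 2] - g[, 1] - len + 1))
    pick <- sample.int(length(weights), 1, prob = weights)
    flat <- do.call(rbind, cand)
    flat_chrom <- rep(names(cand),
                      vapply(cand, nrow, 1L))
    d0 <- flat[pick, 1] +
      floor(stats::runif(1) * (flat[pick, 2] - flat[pick, 1] - len + 1))
    dest <- list(chrom = flat_chrom[pick], start = d0, end = d0 + len)
    # --- record
    events <- rbind(events, data.frame(
      event = e, src_chrom = src$chrom, src_start = src$start,
      src_end = src$end, dest_chrom = dest$chrom, dest_start = dest$start,
      stringsAsFactors = FALSE))
    occ[[src$chrom]] <- rbind(occ[[src$chrom]], c(src$start, src$end))
    occ[[dest$chrom]] <- rbind(occ[[dest$chrom]], c(dest$start, dest$end))
    sides <- rbind(sides,
                   data.frame(chrom = c(src$chrom, dest$chrom),
                              start = c(src$start, dest$start),
                              end = c(src$end, dest$end),
                              stringsAsFactors = FALSE))
  }
  replay_duplication_events(events, n_chroms, chrom_len, min_len,
                            identity_decay)
}

# Base-level copy number: multiplicity of each base's ancestral value.
.copy_number_per_base <- function(history) {
  anc_all <- unlist(history$anc, use.names = FALSE)
  counts <- tabulate(anc_all, nbins = history$n_chroms * history$chrom_len)
  lapply(history$anc, function(a) counts[a])
}

#' Per-region mean copy number from a history
#'
#' True mean copy number over the bases of each region, computed from the
#' base-level ancestry track.
#'
#' @param history `sd_history`.
#' @param regions region table (`chrom`, `start`, `end`).
#' @return numeric vector, one mean per region row.
#' @export
region_copy_number <- function(history, regions) {
  cn <- .copy_number_per_base(history)
  vapply(seq_len(nrow(regions)), function(i) {
    mean(cn[[regions$chrom[i]]][(regions$start[i] + 1):regions$end[i]])
  }, numeric(1))
}

#' Ground-truth network from the event log
#'
#' Independent oracle for the alignment-based pipeline: nodes are maximal
#' strictly-overlapping clusters of the event source/copy intervals; an
#' edge joins two clusters iff they share a colinear common-ancestry run
#' of at least `min_len` bp, determined from the base-level ancestry
#' track (never from the emitted alignments).
#'
#' @param history `sd_history`.
#' @return list `nodes` (data.frame `region_id`, `chrom`, `start`, `end`),
#'   `graph` (simple igraph).
#' @export
ground_truth_network <- function(history) {
  ev <- history$events
  iv <- data.frame(
    chrom = c(ev$src_chrom, ev$dest_chrom),
    start = c(ev$src_start, ev$dest_start),
    end = c(ev$src_end, ev$dest_start + (ev$src_end - ev$src_start)),
    stringsAsFactors = FALSE)
  # strict-overlap merge by sort-scan, per chromosome
  nodes <- NULL
  for (ch in unique(iv$chrom)) {
    sub <- iv[iv$chrom == ch, ]
    sub <- sub[order(sub$start), ]
    cs <- sub$start[1]; ce <- sub$end[1]
    for (r in seq_len(nrow(sub))[-1]) {
      if (sub$start[r] < ce) {
        ce <- max(ce, sub$end[r])
      } else {
        nodes <- rbind(nodes, data.frame(chrom = ch, start = cs, end = ce))
        cs <- sub$start[r]; ce <- sub$end[r]
      }
    }
    nodes <- rbind(nodes, data.frame(chrom = ch, start = cs, end = ce))
  }
  nodes <- nodes[order(nodes$chrom, nodes$start), ]
  nodes$region_id <- seq_len(nrow(nodes))
  # assign every duplicated base a node id, find colinear shared-ancestry
  # runs of >= min_len between nodes
  G <- history$chrom_len
  chrom_index <- stats::setNames(seq_len(history$n_chroms),
                                 paste0("chr", seq_len(history$n_chroms)))
  anc_all <- unlist(history$anc, use.names = FALSE)
  counts <- tabulate(anc_all, nbins = history$n_chroms * G)
  dup_pos <- which(counts[anc_all] >= 2L)       # global 1-based positions
  node_of <- integer(length(anc_all))
  for (i in seq_len(nrow(nodes))) {
    off <- (chrom_index[nodes$chrom[i]] - 1L) * G
    node_of[(off + nodes$start[i] + 1):(off + nodes$end[i])] <- i
  }
  dup_pos <- dup_pos[node_of[dup_pos] > 0]
  v <- anc_all[dup_pos]
  ord <- order(v, dup_pos)
  p <- dup_pos[ord]; vv <- v[ord]
  # group id per sorted entry; expand all within-group pairs by offset
  gi <- cumsum(c(TRUE, diff(vv) != 0))
  max_m <- if (length(gi)) max(tabulate(gi)) else 0L
  pi_ <- list(); pj_ <- list()
  L <- length(p)
  for (o in seq_len(max(0L, max_m - 1L))) {
    idx <- which(gi[seq_len(L - o)] == gi[seq_len(L - o) + o])
    if (length(idx)) {
      pi_[[length(pi_) + 1L]] <- p[idx]
      pj_[[length(pj_) + 1L]] <- p[idx + o]
    }
  }
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  if (length(pi_)) {
    P <- unlist(pi_); Q <- unlist(pj_)
    dt <- data.table::data.table(ni = node_of[P], nj = node_of[Q],
                                 d = Q - P, p = P)
    data.table::setorder(dt, ni, nj, d, p)
    brk <- with(dt, c(TRUE, diff(p) != 1 | diff(d) != 0 |
                        diff(ni) != 0 | diff(nj) != 0))
    dt[, run := cumsum(brk)]
    runs <- dt[, .(len = .N, ni = ni[1], nj = nj[1]), by = run]
    edges <- unique(runs[len >= history$min_len & ni != nj,
                         .(a = pmin(ni, nj), b = pmax(ni, nj))])
    if (nrow(edges)) g <- igraph::add_edges(g, rbind(edges$a, edges$b))
    g <- igraph::simplify(g)
  }
  rownames(nodes) <- NULL
  list(nodes = nodes[, c("region_id", "chrom", "start", "end")], graph = g)
}

#' Simulate a CNV table with a planted degree effect
#'
#' Places `n_cnvs` CNV intervals over duplicated regions and background
#' sequence and draws each minor allele count from a frequency-class
#' mixture whose high-frequency mass increases with the degree of the
#' overlapped region: class log-weights are shifted by
#' `degree_effect * log1p(degree)` toward `high` (and away from `rare`).
#' With `degree_effect = 0` the MAC distribution is independent of degree.
#'
#' @param regions region table with `chrom`, `start`, `end`, `degree`.
#' @param n_cnvs number of CNVs.
#' @param degree_effect nonnegative effect size.
#' @param n_chroms,chrom_len genome shape for background placement.
#' @param cnv_len CNV length, bp.
#' @param prop_background fraction of CNVs placed uniformly rather than on
#'   a region.
#' @param seed RNG seed.
#' @return data.frame `chrom`, `start`, `end`, `mac`.
#' @export
simulate_cnv_table <- function(regions, n_cnvs, degree_effect = 0,
                               n_chroms = 2, chrom_len = 2e5,
                               cnv_len = 500, prop_background = 0.3,
                               seed = NULL) {
  stopifnot(degree_effect >= 0, n_cnvs >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n_cnvs == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), mac = integer()))
  chroms <- paste0("chr", seq_len(n_chroms))
  rows <- vector("list", n_cnvs)
  for (i in seq_len(n_cnvs)) {
    on_region <- nrow(regions) > 0 && stats::runif(1) > prop_background
    if (on_region) {
      j <- sample.int(nrow(regions), 1)
      s0 <- regions$start[j] +
        floor(stats::runif(1) * max(1, regions$end[j] - regions$start[j] -
                                      cnv_len))
      ch <- regions$chrom[j]
      k <- regions$degree[j]
    } else {
      ch <- chroms[sample.int(n_chroms, 1)]
      s0 <- floor(stats::runif(1) * (chrom_len - cnv_len))
      k <- 0
    }
    lw <- c(rare = 1.1, medium = 0.3, high = -1.4)
    lw["high"] <- lw["high"] + degree_effect * log1p(k)
    lw["rare"] <- lw["rare"] - degree_effect * log1p(k)
    pr <- exp(lw) / sum(exp(lw))
    cls <- sample(names(pr), 1, prob = pr)
    mac <- switch(cls,
                  rare = sample(1:3, 1),
                  medium = sample(4:15, 1),
                  high = round(exp(stats::runif(1, log(16), log(2504)))))
    rows[[i]] <- data.frame(chrom = ch, start = s0, end = s0 + cnv_len,
                            mac = as.integer(mac),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
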
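# Merging alignment sides into duplicated regions and building the
# trimmed/untrimmed network.

test_that("the two-alignment toy merges into three regions and two edges", {
  alns <- sd_alignments(c("chr1", "chr1"), c(100, 1500), c(2100, 2600),
                        c("chr1", "chr2"), c(5000, 100), c(7000, 1200),
                        identity = 0.95)
  m <- merge_to_regions(alns)
  expect_equal(nrow(m$regions), 3L)
  expect_equal(m$regions$chrom, c("chr1", "chr1", "chr2"))
  expect_equal(m$regions$start, c(100L, 5000L, 100L))
  expect_equal(m$regions$end, c(2600L, 7000L, 1200L))
  net <- build_network(m$regions, m$side_to_region, alns)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  expect_length(net$self_loops, 0L)
})

test_that("a single alignment yields two regions equal to its sides", {
  alns <- sd_alignments("chr1", 100, 2100, "chr1", 9000, 11000)
  m <- merge_to_regions(alns)
  expect_equal(nrow(m$regions), 2L)
  expect_equal(m$regions$start, c(100L, 9000L))
  expect_equal(m$regions$end, c(2100L, 11000L))
})

test_that("touching half-open intervals merge only under positive padding", {
  alns <- sd_alignments("chr1", 0, 1000, "chr1", 1000, 2000)
  expect_equal(nrow(merge_to_regions(alns, padding = 0)$regions), 2L)
  merged <- merge_to_regions(alns, padding = 1)
  expect_equal(nrow(merged$regions), 1L)
  # region bounds stay unpadded
  expect_equal(merged$regions$start, 0L)
  expect_equal(merged$regions$end, 2000L)
  # the padded-merge alignment becomes a self-loop
  net <- build_network(merged$regions, merged$side_to_region, alns)
  expect_equal(nrow(net$edges), 0L)
  expect_equal(unname(net$self_loops), 1L)
})

test_that("overlapping sides of one alignment give a self-loop node", {
  alns <- sd_alignments("chr1", 100, 2000, "chr1", 1500, 3000)
  m <- merge_to_regions(alns)
  expect_equal(nrow(m$regions), 1L)
  net <- build_network(m$regions, m$side_to_region, alns)
  expect_equal(unname(net$self_loops), 1L)
  expect_equal(nrow(net$edges), 0L)
})

test_that("negative padding larger than a side errors", {
  alns <- sd_alignments("chr1", 0, 1000, "chr1", 5000, 6000)
  expect_error(merge_to_regions(alns, padding = -500), "padding")
})

test_that("merging is idempotent on disjoint sides", {
  alns <- sd_alignments(c("chr1", "chr2"), c(0, 0), c(1000, 1500),
                        c("chr1", "chr2"), c(5000, 8000), c(6000, 9500))
  m <- merge_to_regions(alns)
  expect_equal(nrow(m$regions), 4L)
  expect_equal(sort(m$regions$length), sort(c(1000L, 1000L, 1500L, 1500L)))
})

test_that("regions match the brute-force pairwise closure on random tables", {
  for (seed in 1:10) {
    set.seed(seed)
    alns <- random_alignments(sample(10:50, 1))
    P <- sample(c(0, 0, 100, 250), 1)
    m <- merge_to_regions(alns, padding = P)
    oracle <- brute_force_regions(
      c(alns$chrom_a, alns$chrom_b), c(alns$start_a, alns$start_b),
      c(alns$end_a, alns$end_b), padding = P)
    got <- m$regions[order(m$regions$chrom, m$regions$start),
                     c("chrom", "start", "end")]
    rownames(got) <- NULL
    expect_equal(got, oracle)
    # partition invariant: every side maps to exactly one region
    expect_equal(length(m$side_to_region), 2L * nrow(alns))
    expect_true(all(m$side_to_region >= 1 &
                      m$side_to_region <= nrow(m$regions)))
  }
})

test_that("padding monotonicity: fewer regions, at least as many self-loops", {
  set.seed(11)
  alns <- random_alignments(40)
  prev_regions <- Inf; prev_loops <- -1
  for (P in c(0, 200, 1000, 5000)) {
    m <- merge_to_regions(alns, padding = P)
    net <- build_network(m$regions, m$side_to_region, alns)
    expect_lte(nrow(m$regions), prev_regions)
    expect_gte(sum(net$self_loops), prev_loops)
    prev_regions <- nrow(m$regions); prev_loops <- sum(net$self_loops)
  }
})

test_that("untrimmed multiplicities account for every alignment", {
  set.seed(12)
  alns <- random_alignments(60)
  net <- sd_network_from_alignments(alns, min_len = 0, min_identity = 0,
                                    autosomes_only = FALSE)
  expect_equal(sum(net$edges$multiplicity) + sum(net$self_loops),
               nrow(alns))
  expect_lte(igraph::ecount(net$graph), nrow(alns))
  expect_equal(net$nodes$degree, igraph::degree(net$graph))
})

test_that("network IO round-trips", {
  set.seed(13)
  alns <- random_alignments(30)
  net <- sd_network_from_alignments(alns, min_len = 0, min_identity = 0,
                                    autosomes_only = FALSE)
  dir <- withr::local_tempdir()
  write_sd_network(net, dir)
  back <- read_sd_network(dir)
  expect_equal(back$nodes, net$nodes)
  expect_equal(back$edges, net$edges)
  expect_true(igraph::isomorphic(back$graph, net$graph))
})
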
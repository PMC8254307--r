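# Component spectra, binned densities, slope fits, giant-component stats,
# reference networks, modules and edge classes.

test_that("component spectrum decomposes a triangle plus an edge", {
  g <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5)), directed = FALSE)
  sp <- component_spectrum(g)
  expect_equal(sp$sizes, c(3L, 2L))
  expect_equal(sp$edges, c(3L, 1L))
  expect_equal(unname(motif_counts(sp)), c(1, 0, 1, 0))
  expect_equal(sp$mean_edges_by_size$mean_E, c(1, 3))
})

test_that("spectrum conserves node and edge totals on random graphs", {
  for (seed in 1:5) {
    set.seed(seed)
    g <- igraph::sample_gnp(200, 0.01)
    sp <- component_spectrum(g)
    expect_equal(sum(sp$sizes), igraph::vcount(g))
    expect_equal(sum(sp$edges), igraph::ecount(g))
    expect_true(all(sp$edges >= sp$sizes - 1))
  }
})

test_that("log binning conserves counts and handles degenerate input", {
  set.seed(21)
  v <- sample(1:500, 2000, replace = TRUE)
  d <- log_binned_density(v)
  expect_equal(sum(d$count), length(v))
  expect_true(all(diff(d$hi / d$lo) < 1e-9))  # geometric bins
  one <- log_binned_density(rep(7, 50))
  expect_equal(sum(one$count > 0), 1L)
  expect_error(log_binned_density(c(1, 0)), "positive")
})

test_that("log-log slope fit is exact on power-law data", {
  x <- c(2, 5, 10, 30, 100)
  expect_equal(fit_loglog_slope(x, x^1.5)$slope, 1.5, tolerance = 1e-10)
  expect_equal(fit_loglog_slope(x, rep(4, 5))$slope, 0, tolerance = 1e-10)
  expect_error(fit_loglog_slope(rep(3, 5), x), "degenerate")
})

test_that("binned-density regression recovers a sampled power-law exponent", {
  set.seed(22)
  N <- 1:10^4
  v <- sample(N, 1e5, replace = TRUE, prob = N^-2.7)
  fit <- spectrum_slope(v)
  expect_equal(fit$slope, -2.7, tolerance = 0.1 / 2.7)
})

test_that("giant-component stats are exact on closed-form graphs", {
  k4 <- igraph::make_full_graph(4)
  st <- giant_component_stats(k4)
  expect_equal(st$clustering, 1)
  expect_equal(st$path_length, 1)
  star <- igraph::make_star(5, mode = "undirected")
  st <- giant_component_stats(star)
  expect_equal(st$clustering, 0)
  expect_equal(st$path_length, 1.6)  # 4 pairs at 1, 6 pairs at 2
})

test_that("reference networks honour their size contracts", {
  er <- reference_network("er", n = 1325, m = 9678, seed = 1)
  expect_equal(igraph::vcount(er), 1325)
  expect_equal(igraph::ecount(er), 9678)
  ba <- reference_network("ba", n = 500, k = 7, seed = 2)
  expect_equal(igraph::vcount(ba), 500)
  # BA bookkeeping: k edges per new node once k seeds exist
  expect_equal(igraph::ecount(ba), 7 * (500 - 7) + choose(7, 2))
  expect_equal(mean(igraph::degree(ba)), 2 * igraph::ecount(ba) / 500)
  degs <- igraph::degree(igraph::sample_gnm(300, 900))
  cfg <- reference_network("config", degrees = degs, seed = 3)
  # erased multi-edges/self-loops only ever reduce degrees
  expect_true(all(igraph::degree(cfg) <= degs))
  expect_gte(sum(igraph::degree(cfg)), 0.9 * sum(degs))
  expect_error(reference_network("config", degrees = c(3, 2)), "odd")
})

test_that("G(n,m) clustering concentrates near 2m/(n(n-1))", {
  cc <- mean(sapply(1:5, function(s) {
    giant_component_stats(
      reference_network("er", n = 1325, m = 9678, seed = s))$clustering
  }))
  expected <- 2 * 9678 / (1325 * 1324)
  expect_lt(abs(cc - expected) / expected, 0.25)
})

test_that("label propagation separates weakly joined cliques", {
  two_tri <- igraph::graph_from_edgelist(
    rbind(c(1, 2), c(2, 3), c(1, 3), c(4, 5), c(5, 6), c(4, 6), c(3, 4)),
    directed = FALSE)
  mods <- detect_modules(two_tri, seed = 5)
  expect_equal(length(unique(mods)), 2L)
  expect_equal(mods[1], mods[2])
  expect_equal(mods[4], mods[6])
  expect_false(mods[1] == mods[6])
  full <- detect_modules(igraph::make_full_graph(8), seed = 1)
  expect_equal(length(unique(full)), 1L)
})

test_that("edge classes split into intra/inter and tandem", {
  nodes <- data.frame(region_id = 1:4,
                      chrom = c("chr1", "chr1", "chr2", "chr2"),
                      start = c(0, 4e5, 0, 7e5),
                      end = c(1e3, 401e3, 1e3, 701e3))
  # inter, intra+tandem (gap 399 kb), intra non-tandem (gap 699 kb)
  edges <- data.frame(a = c(1, 1, 3), b = c(3, 2, 4),
                      multiplicity = 1L)
  net <- manual_network(nodes, edges)
  fr <- edge_class_fractions(net)
  expect_equal(fr$intra_fraction, 2 / 3)
  expect_equal(fr$tandem_fraction, 1 / 3)
  inter_only <- manual_network(nodes,
                               data.frame(a = 1, b = 3, multiplicity = 1L))
  expect_equal(edge_class_fractions(inter_only),
               list(intra_fraction = 0, tandem_fraction = 0))
})
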
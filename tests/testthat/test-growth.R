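# Kinetic Monte Carlo growth under the uniform and preferential copying
# models.

test_that("rates vectors follow the model definitions", {
  p_pcm <- growth_params("pcm", delta = 0.1, f = 0.5, target_nodes = 10)
  p_ucm <- growth_params("ucm", delta = 0.1, f = 0.5, target_nodes = 10)
  expect_equal(rates_vector(NULL, p_pcm), 1)
  c21 <- igraph::graph_from_edgelist(rbind(c(1, 2)), directed = FALSE)
  expect_equal(rates_vector(c21, p_pcm), c(1, 0.1, 0.1))
  expect_equal(rates_vector(c21, p_ucm), c(1, 0.1, 0.1))
  tri <- igraph::make_full_graph(3)
  path3 <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3)),
                                       directed = FALSE)
  r_tri <- sum(rates_vector(tri, p_pcm)[-1])
  r_path <- sum(rates_vector(path3, p_pcm)[-1])
  # C(3,3) duplicates 1.5x faster than C(3,2) under the PCM
  expect_equal(r_tri / r_path, 1.5)
  # incremental degree bookkeeping agrees with full recomputation
  sim <- simulate_growth(growth_params("pcm", delta = 0.01, f = 0.5,
                                       target_nodes = 200, seed = 1))
  g <- growth_as_igraph(sim)
  expect_equal(sim$degree, igraph::degree(g))
})

test_that("kmc_draw picks events by rate and exponential waiting times", {
  set.seed(31)
  draws <- replicate(2e4, kmc_draw(c(1, 0.5, 0.5))$event)
  expect_equal(mean(draws == 1), 0.5, tolerance = 0.03)
  expect_equal(mean(draws == 2), 0.25, tolerance = 0.05)
  dts <- replicate(2e4, kmc_draw(2)$dt)
  expect_equal(mean(dts), 0.5, tolerance = 0.03)
  # KS against Exponential(R) for fixed total rate R
  R <- 1.7
  dts <- replicate(1e4, kmc_draw(c(R / 2, R / 2))$dt)
  expect_gt(stats::ks.test(dts, stats::pexp, rate = R)$p.value, 0.01)
  expect_error(kmc_draw(c(0, 0)), "zero")
})

test_that("node duplication inherits edges binomially", {
  star <- igraph::make_star(11, mode = "undirected", center = 1)
  # mother = hub with degree 10
  res1 <- duplicate_node(star, 1, f = 1)
  expect_equal(igraph::degree(res1$graph, res1$daughter), 11)
  res0 <- duplicate_node(star, 1, f = 0)
  expect_equal(igraph::degree(res0$graph, res0$daughter), 1)
  set.seed(32)
  kd <- replicate(400, {
    r <- duplicate_node(star, 1, f = 0.5)
    igraph::degree(r$graph, r$daughter)
  })
  expect_equal(mean(kd), 1 + 0.5 * 10, tolerance = 0.3 / 6)
})

test_that("edge loss removes a binomial number of edges", {
  g <- igraph::sample_gnm(300, 1000)
  expect_equal(apply_edge_loss(g, 0)$removed, 0L)
  set.seed(33)
  rem <- apply_edge_loss(g, 0.1)$removed
  expect_lt(abs(rem - 100), 3 * sqrt(90))
})

test_that("delta = 0 yields only de novo C(2,1) components", {
  sim <- simulate_growth(growth_params("ucm", delta = 0, f = 0.5,
                                       target_nodes = 100, seed = 2))
  expect_true(all(sim$components$sizes == 2))
  expect_true(all(sim$components$edges == 1))
})

test_that("f = 0 growth produces only tree components", {
  for (model in c("ucm", "pcm")) {
    sim <- simulate_growth(growth_params(model, delta = 0.02, f = 0,
                                         target_nodes = 500, seed = 3))
    expect_true(all(sim$components$edges == sim$components$sizes - 1))
  }
})

test_that("f = 1 keeps complete components complete", {
  sim <- simulate_growth(growth_params("pcm", delta = 0.02, f = 1,
                                       target_nodes = 300, seed = 4))
  expect_true(all(sim$components$edges ==
                    choose(sim$components$sizes, 2)))
})

test_that("event log bookkeeping matches the realized network", {
  sim <- simulate_growth(growth_params("pcm", delta = 0.01, f = 0.5,
                                       target_nodes = 400, seed = 5))
  n_add <- sum(sim$events$type == "add")
  n_dup <- sum(sim$events$type == "dup")
  expect_equal(sim$n_nodes, 2L * n_add + n_dup)
  expect_true(all(diff(sim$events$time) > 0))
  # edge count: 1 per addition, 1 + inherited per duplication
  expect_equal(nrow(sim$edges),
               n_add + n_dup + sum(lengths(
                 sim$events$inherited[sim$events$type == "dup"])))
  # component bookkeeping agrees with an igraph recomputation
  sp <- component_spectrum(growth_as_igraph(sim))
  expect_equal(sort(sim$components$sizes), sort(sp$sizes))
  expect_equal(sum(sim$components$edges), sum(sp$edges))
})

test_that("identical parameters and seed reproduce the event log", {
  p <- growth_params("pcm", delta = 0.01, f = 0.4, target_nodes = 300,
                     seed = 6)
  s1 <- simulate_growth(p); s2 <- simulate_growth(p)
  expect_identical(s1$events, s2$events)
  expect_identical(s1$edges, s2$edges)
  expect_identical(s1$time, s2$time)
})

test_that("edge loss keeps node bookkeeping and loses edges", {
  p <- growth_params("pcm", delta = 0.01, f = 0.5, target_nodes = 300,
                     edge_loss_r = 0.05, seed = 7)
  sim <- simulate_growth(p)
  n_add <- sum(sim$events$type == "add")
  n_dup <- sum(sim$events$type == "dup")
  expect_equal(sim$n_nodes, 2L * n_add + n_dup)
  expect_lt(nrow(sim$edges),
            n_add + n_dup + sum(lengths(sim$events$inherited)))
  # spectrum recomputed from the realized graph
  expect_equal(sum(sim$components$sizes), sim$n_nodes)
})

test_that("pooling one replicate equals the single underlying run", {
  p <- growth_params("pcm", delta = 0.01, f = 0.5, target_nodes = 200,
                     seed = 8)
  pooled <- pool_simulations(p, n_reps = 1)
  set.seed(8)
  p1 <- p; p1$seed <- sample.int(.Machine$integer.max, 1)
  single <- simulate_growth(p1, record_log = FALSE)
  expect_equal(pooled$sizes, single$components$sizes)
  expect_equal(pooled$degrees, single$degree)
})

test_that("pooled PCM edge scaling recovers 1 + f", {
  # E(N) ~ N^(1+f) is an asymptotic law: the duplication depth must be
  # large enough for components to span several size decades, and deeper
  # for small f where the pre-asymptotic inflation is strongest
  cases <- list(list(f = 0.3, delta = 2e-3, target = 5000),
                list(f = 0.7, delta = 5e-4, target = 3000))
  for (cs in cases) {
    pooled <- pool_simulations(
      growth_params("pcm", delta = cs$delta, f = cs$f,
                    target_nodes = cs$target,
                    seed = 40 + round(10 * cs$f)), n_reps = 40)
    est <- estimate_f_regression(pooled$mean_edges_by_size)
    expect_equal(est$slope, 1 + cs$f, tolerance = 0.1 / (1 + cs$f))
  }
})
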
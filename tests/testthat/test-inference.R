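# Parameter inference: edge-scaling regression, motif-count ODE loss,
# Bray-Curtis ABC, and the giant-component p-value.

test_that("f regression is exact on closed-form edge scaling", {
  df <- data.frame(N = c(2, 3, 5, 10, 40), mean_E = c(2, 3, 5, 10, 40)^1.5)
  est <- estimate_f_regression(df)
  expect_equal(est$f, 0.5, tolerance = 1e-10)
  expect_error(estimate_f_regression(df[1:2, ]), "3")
})

test_that("motif counts pick out C(2,1), C(3,2), C(3,3) and C(>3,*)", {
  path3 <- igraph::graph_from_edgelist(rbind(c(1, 2), c(2, 3)),
                                       directed = FALSE)
  expect_equal(unname(motif_counts(path3)), c(0, 1, 0, 0))
  expect_equal(unname(motif_counts(igraph::make_full_graph(3))),
               c(0, 0, 1, 0))
  mix <- igraph::disjoint_union(
    igraph::graph_from_edgelist(rbind(c(1, 2)), directed = FALSE),
    igraph::graph_from_edgelist(rbind(c(1, 2)), directed = FALSE),
    igraph::graph_from_edgelist(rbind(c(1, 2)), directed = FALSE),
    igraph::make_full_graph(4))
  expect_equal(unname(motif_counts(mix)), c(3, 0, 0, 1))
})

test_that("closed-form motif counts satisfy limits and the ODE system", {
  expect_equal(unname(ode_motif_counts(0.4, 3e-4, 0)), rep(0, 4))
  # t -> infinity plateaus for the three transient classes
  lim <- ode_motif_counts(0.4, 3e-4, 1e9)
  expect_equal(lim[["n21"]], 1 / (2 * 3e-4), tolerance = 1e-8)
  expect_equal(lim[["n32"]], (1 - 0.4) / (4 * 3e-4), tolerance = 1e-8)
  expect_equal(lim[["n33"]], 0.4 / (6 * 3e-4), tolerance = 1e-8)
  expect_error(ode_motif_counts(0.4, 0, 10), "delta")
  # numerical integration oracle (Runge-Kutta via deSolve)
  rhs <- function(t, y, p) {
    with(as.list(p), list(c(
      1 - 2 * delta * y[1],
      2 * delta * (1 - f) * y[1] - 4 * delta * y[2],
      2 * delta * f * y[1] - 6 * delta * y[3],
      4 * delta * y[2] + 6 * delta * y[3])))
  }
  for (cfg in list(c(0.3, 2e-4, 800), c(0.52, 3.2e-4, 1320),
                   c(0.9, 5e-3, 150))) {
    sol <- deSolve::ode(y = rep(0, 4), times = c(0, cfg[3]), func = rhs,
                        parms = c(f = cfg[1], delta = cfg[2]),
                        method = "ode45", rtol = 1e-12, atol = 1e-12)
    got <- ode_motif_counts(cfg[1], cfg[2], cfg[3])
    expect_equal(unname(got), unname(sol[2, -1]), tolerance = 1e-8)
  }
})

test_that("the city-block loss matches hand arithmetic", {
  expect_equal(loss_L(c(1, 2, 3, 4), c(1, 2, 3, 4)), 0)
  expect_equal(loss_L(c(2, 1, 1, 1), c(1, 1, 2, 2)), 1 + 0 + 0.5 + 0.5)
  expect_error(loss_L(c(1, 1, 1, 1), c(1, 0, 1, 1)), "positive")
})

test_that("loss minimisation recovers planted parameters", {
  truth <- c(f = 0.5, delta = 4e-4, t = 1000)
  n_obs <- ode_motif_counts(truth[1], truth[2], truth[3])
  fit <- minimize_loss(n_obs, seed = 9)
  expect_lt(fit$loss, 1e-6)
  expect_equal(fit$f, 0.5, tolerance = 0.01)
  expect_equal(fit$delta, 4e-4, tolerance = 0.01)
  expect_equal(fit$t, 1000, tolerance = 0.01)
  # independent restarts land on the same optimum
  fit2 <- minimize_loss(n_obs, start = c(0.3, 1e-4, 300), seed = 99)
  expect_equal(fit2$f, fit$f, tolerance = 0.02)
})

test_that("bray_curtis matches hand values and vegan", {
  expect_equal(bray_curtis(c(3, 2, 1), c(3, 2, 1)), 0)
  expect_equal(bray_curtis(c(3, 2, 1), c(1, 2, 3)), 1 / 3)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_error(bray_curtis(1:3, 1:4), "length")
  set.seed(41)
  for (i in 1:5) {
    x <- rpois(20, 5); y <- rpois(20, 5)
    d <- bray_curtis(x, y)
    expect_equal(d, bray_curtis(y, x))
    expect_gte(d, 0); expect_lte(d, 1)
    expect_equal(d, as.numeric(vegan::vegdist(rbind(x, y), "bray")))
  }
})

test_that("wide-open ABC returns the prior; seeds reproduce", {
  set.seed(42)
  obs <- simulate_growth(growth_params("pcm", delta = 4e-4, f = 0.47,
                                       target_nodes = 600, seed = 1),
                         record_log = FALSE)$components$sizes
  res <- abc_delta(obs, f = 0.47, prior = c(1e-4, 9e-4), n_sims = 60,
                   tolerance = 1.5, target_nodes = 400, seed = 7)
  expect_equal(res$acceptance_rate, 1)
  expect_equal(res$estimate, 5e-4, tolerance = 0.15)
  res2 <- abc_delta(obs, f = 0.47, prior = c(1e-4, 9e-4), n_sims = 60,
                    tolerance = 1.5, target_nodes = 400, seed = 7)
  expect_identical(res$accepted, res2$accepted)
  expect_error(
    abc_delta(obs, f = 0.47, n_sims = 5, tolerance = 1e-9,
              target_nodes = 400, seed = 1),
    "tolerance")
})

test_that("the empirical giant-component p-value is calibrated", {
  sims <- 1:199
  expect_equal(giant_component_pvalue(100, sims), 1)
  expect_lte(giant_component_pvalue(500, sims), 2 / 199)
  expect_equal(giant_component_pvalue(500, sims, sided = "one"), 0)
  expect_equal(giant_component_pvalue(50, sims),
               2 * mean(sims <= 50))
})
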
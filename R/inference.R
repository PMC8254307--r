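# Inference of the preferential copying model parameters (f, delta, t)
# by three independent routes: log-log regression of edges-per-component
# scaling, ABC rejection on component spectra, and minimisation of a
# weighted city-block loss between observed motif counts and the
# closed-form solution of the motif-count ODE system.

#' Estimate f from the edges-per-component scaling
#'
#' In the PCM the mean number of edges E in components of N nodes scales as
#' E proportional to N^(1+f) for large N, so the fitted log-log slope minus
#' one estimates f.
#'
#' @param mean_edges_by_size data.frame with columns `N` and `mean_E`
#'   (one point per observed component size), as produced by
#'   [component_spectrum()] or [pool_simulations()].
#' @param include_giant keep the largest-size point (the giant component)
#'   in the regression.
#' @return list `f`, `slope`, `stderr`.
#' @export
estimate_f_regression <- function(mean_edges_by_size,
                                  include_giant = TRUE) {
  df <- mean_edges_by_size[order(mean_edges_by_size$N), ]
  if (!include_giant) df <- df[-nrow(df), ]
  if (nrow(df) < 3) stop("need at least 3 component sizes")
  fit <- fit_loglog_slope(df$N, df$mean_E)
  list(f = fit$slope - 1, slope = fit$slope, stderr = fit$stderr)
}

#' Count the small-component motifs
#'
#' Counts of components C(2,1), C(3,2) (three-node paths), C(3,3)
#' (triangles) and C(>3,*) (all components with more than 3 nodes) in a
#' trimmed simple graph.
#'
#' @param network `sd_network`, `sd_growth`, igraph, or a
#'   `component_spectrum`.
#' @return named numeric vector `c(n21, n32, n33, n_gt3)`.
#' @export
motif_counts <- function(network) {
  sp <- if (inherits(network, "component_spectrum")) network
        else if (inherits(network, "sd_growth"))
          list(sizes = network$components$sizes,
               edges = network$components$edges)
        else component_spectrum(network)
  N <- sp$sizes; E <- sp$edges
  c(n21 = sum(N == 2),
    n32 = sum(N == 3 & E == 2),
    n33 = sum(N == 3 & E == 3),
    n_gt3 = sum(N > 3))
}

#' Expected motif counts under the PCM at time t
#'
#' Closed-form solution of the motif-count ODE system
#' \deqn{dn(2,1)/dt = 1 - 2 d n(2,1)}
#' \deqn{dn(3,2)/dt = 2 d (1-f) n(2,1) - 4 d n(3,2)}
#' \deqn{dn(3,3)/dt = 2 d f n(2,1) - 6 d n(3,3)}
#' \deqn{dn(>3,*)/dt = 4 d n(3,2) + 6 d n(3,3)}
#' started from an empty network. The C(>3,*) class only accumulates, so
#' its solution grows asymptotically linearly in t.
#'
#' @param f inheritance probability in \[0, 1\].
#' @param delta duplication rate (> 0).
#' @param t elapsed time (>= 0).
#' @return named numeric vector `c(n21, n32, n33, n_gt3)`.
#' @export
ode_motif_counts <- function(f, delta, t) {
  stopifnot(f >= 0, f <= 1, t >= 0)
  if (delta <= 0) stop("delta must be positive")
  e2 <- exp(-2 * delta * t); e4 <- exp(-4 * delta * t)
  e6 <- exp(-6 * delta * t)
  n21 <- (1 - e2) / (2 * delta)
  n32 <- (1 - f) * (1 - 2 * e2 + e4) / (4 * delta)
  n33 <- f * (1 - 1.5 * e2 + 0.5 * e6) / (6 * delta)
  n_gt3 <- t + (f - 9 + 3 * (4 - f) * e2 - 3 * (1 - f) * e4 - f * e6) /
    (12 * delta)
  c(n21 = n21, n32 = n32, n33 = n33, n_gt3 = n_gt3)
}

#' Weighted city-block loss between motif-count vectors
#'
#' `L = sum_i |n_t[i] - n_obs[i]| / n_obs[i]` over the four motif classes.
#'
#' @param n_t expected counts (real-valued).
#' @param n_obs observed counts (all > 0).
#' @return scalar loss.
#' @export
loss_L <- function(n_t, n_obs) {
  stopifnot(length(n_t) == 4, length(n_obs) == 4)
  if (any(n_obs <= 0)) stop("observed motif counts must all be positive")
  sum(abs(n_t - n_obs) / n_obs)
}

#' Fit (f, delta, t) by minimising the motif-count loss
#'
#' Nelder-Mead in transformed coordinates (logit f, log delta, log t) so
#' the constraints f in \[0,1\], delta > 0, t > 0 hold automatically; the
#' default start is jittered into several restarts and the best optimum is
#' kept.
#'
#' @param n_obs observed motif counts (`c(n21, n32, n33, n_gt3)`, all > 0).
#' @param start starting values `c(f, delta, t)`.
#' @param n_restarts number of jittered restarts.
#' @param seed RNG seed for the jitter.
#' @return list `f`, `delta`, `t`, `loss`, `converged`.
#' @export
minimize_loss <- function(n_obs, start = c(f = 0.5, delta = 1e-3 * exp(-1),
                                           t = 1e3),
                          n_restarts = 5, seed = NULL) {
  stopifnot(all(n_obs > 0))
  if (!is.null(seed)) set.seed(seed)
  obj <- function(par) {
    f <- stats::plogis(par[1]); delta <- exp(par[2]); tt <- exp(par[3])
    loss_L(ode_motif_counts(f, delta, tt), n_obs)
  }
  p0 <- c(stats::qlogis(min(max(start[1], 1e-6), 1 - 1e-6)),
          log(start[2]), log(start[3]))
  best <- NULL
  for (i in seq_len(max(1, n_restarts))) {
    init <- if (i == 1) p0 else p0 + stats::rnorm(3, sd = 0.5)
    fit <- stats::optim(init, obj, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  list(f = unname(stats::plogis(best$par[1])),
       delta = unname(exp(best$par[2])), t = unname(exp(best$par[3])),
       loss = best$value, converged = best$convergence == 0)
}

#' Bray-Curtis dissimilarity
#'
#' `D = sum(|x - y|) / sum(x + y)` for nonnegative vectors of equal
#' length; 0 for identical vectors, 1 for disjoint support.
#'
#' @param x,y nonnegative numeric vectors of the same length, not both
#'   all-zero.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  denom <- sum(x + y)
  if (denom == 0) stop("both vectors are all-zero")
  sum(abs(x - y)) / denom
}

# Sorted-descending top-n component-size vector, zero-padded.
top_sizes <- function(sizes, top_n = 500) {
  s <- sort(sizes, decreasing = TRUE)
  out <- numeric(top_n)
  k <- min(top_n, length(s))
  out[seq_len(k)] <- s[seq_len(k)]
  out
}

#' ABC rejection estimate of delta
#'
#' Draws delta uniformly from the prior, simulates the PCM to
#' `target_nodes` with the given f, and accepts draws whose sorted
#' top-`top_n` component-size vector (zero-padded) is within `tolerance`
#' Bray-Curtis dissimilarity of the observed one. The point estimate is
#' the posterior mean; the 95% band is the 2.5/97.5 percentile interval.
#'
#' @param observed_sizes component-size vector of the observed network.
#' @param f inheritance probability (held fixed; the paper-scale analysis
#'   uses the regression estimate).
#' @param prior uniform prior interval for delta.
#' @param n_sims number of simulations (paper scale: 5000).
#' @param tolerance Bray-Curtis acceptance threshold.
#' @param top_n spectrum vector length.
#' @param target_nodes simulation termination size.
#' @param seed RNG seed.
#' @return list of class `abc_result`: `accepted` (delta draws),
#'   `estimate`, `ci` (2.5/97.5 percentiles), `acceptance_rate`,
#'   `n_sims`, `tolerance`, `prior`.
#' @export
abc_delta <- function(observed_sizes, f, prior = c(5e-5, 9e-4),
                      n_sims = 5000, tolerance = 0.2, top_n = 500,
                      target_nodes = 6656, seed = NULL) {
  stopifnot(prior[1] > 0, prior[2] > prior[1], length(observed_sizes) > 0)
  if (!is.null(seed)) set.seed(seed)
  obs <- top_sizes(observed_sizes, top_n)
  deltas <- stats::runif(n_sims, prior[1], prior[2])
  sim_seeds <- sample.int(.Machine$integer.max, n_sims)
  accepted <- logical(n_sims)
  for (i in seq_len(n_sims)) {
    p <- growth_params("pcm", delta = deltas[i], f = f,
                       target_nodes = target_nodes, seed = sim_seeds[i])
    sim <- simulate_growth(p, record_log = FALSE)
    d <- bray_curtis(top_sizes(sim$components$sizes, top_n), obs)
    accepted[i] <- d < tolerance
  }
  acc <- deltas[accepted]
  if (!length(acc))
    stop("no ABC acceptances; increase the tolerance or the prior range")
  structure(list(accepted = acc, estimate = mean(acc),
                 ci = unname(stats::quantile(acc, c(0.025, 0.975))),
                 acceptance_rate = mean(accepted), n_sims = n_sims,
                 tolerance = tolerance, prior = prior),
            class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat(sprintf(
    "ABC: delta = %.3g, 95%% CI [%.3g, %.3g], %d/%d accepted\n",
    x$estimate, x$ci[1], x$ci[2], length(x$accepted), x$n_sims))
  invisible(x)
}

#' Empirical p-value for the observed giant-component size
#'
#' Position of the observed giant-component size within the empirical
#' distribution of the biggest components of replicate simulations.
#' Two-sided by default: `p = min(1, 2 * min(P(X <= x), P(X >= x)))`.
#'
#' @param observed observed giant-component size.
#' @param simulated vector of simulated biggest-component sizes (>= 100).
#' @param sided `"two"` or `"one"` (upper tail).
#' @return empirical p-value.
#' @export
giant_component_pvalue <- function(observed, simulated,
                                   sided = c("two", "one")) {
  sided <- match.arg(sided)
  if (length(simulated) < 100)
    warning("fewer than 100 simulated values; p-value is coarse")
  lo <- mean(simulated <= observed)
  hi <- mean(simulated >= observed)
  if (sided == "one") hi else min(1, 2 * min(lo, hi))
}
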
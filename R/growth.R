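# Kinetic Monte Carlo simulation of network growth under the uniform
# (UCM) and preferential (PCM) copying models. Two processes: a new
# two-node component C(2,1) appears with rate pi, and any existing node i
# is duplicated with rate delta (UCM) or delta * k_i (PCM). A daughter
# node always gains the mother-daughter edge and inherits each
# mother-neighbour edge independently with probability f.

#' Growth-model parameters
#'
#' @param model `"ucm"` or `"pcm"`.
#' @param delta duplication rate scale (> 0); only delta/pi matters, so pi
#'   is fixed at 1.
#' @param f edge-inheritance probability in \[0, 1\].
#' @param target_nodes stop once the node count reaches this threshold.
#' @param edge_loss_r per-edge removal probability applied after every
#'   event (0 disables).
#' @param pi component-addition rate (fixed 1 by convention).
#' @param seed RNG seed (optional).
#' @return list of class `growth_params`.
#' @export
growth_params <- function(model = c("pcm", "ucm"), delta, f,
                          target_nodes, edge_loss_r = 0, pi = 1,
                          seed = NULL) {
  model <- match.arg(model)
  stopifnot(delta >= 0, f >= 0, f <= 1, target_nodes >= 2,
            edge_loss_r >= 0, edge_loss_r < 1, pi > 0)
  structure(list(model = model, pi = pi, delta = delta, f = f,
                 target_nodes = as.integer(target_nodes),
                 edge_loss_r = edge_loss_r, seed = seed),
            class = "growth_params")
}

#' Rates vector of all possible processes
#'
#' Element 1 is the component-addition rate pi; element `i + 1` is the
#' duplication rate of node `i`: delta for the UCM, delta * k_i for the
#' PCM, with k_i the node's current degree in the simple graph.
#'
#' @param network igraph / `sd_network` / `sd_growth` (or NULL for the
#'   empty network).
#' @param params `growth_params`.
#' @return numeric vector of length N + 1.
#' @export
rates_vector <- function(network, params) {
  if (is.null(network)) return(params$pi)
  g <- .as_igraph(network)
  k <- igraph::degree(g)
  dup <- if (params$model == "ucm") rep(params$delta, length(k))
         else params$delta * k
  c(params$pi, dup)
}

#' One kinetic Monte Carlo draw
#'
#' Picks event `i` with probability `rates[i] / sum(rates)` and samples the
#' exponential waiting time `dt = -log(u) / sum(rates)` with
#' `u ~ Uniform(0, 1]`.
#'
#' @param rates nonnegative rates with positive sum.
#' @return list `event` (index into `rates`), `dt`.
#' @export
kmc_draw <- function(rates) {
  total <- sum(rates)
  if (total <= 0) stop("all rates are zero")
  ev <- sample.int(length(rates), 1L, prob = rates)
  dt <- -log(1 - stats::runif(1)) / total
  list(event = ev, dt = dt)
}

#' Duplicate one node of a graph
#'
#' Adds a daughter node joined to `mother` and, independently with
#' probability `f`, to each of the mother's neighbours.
#'
#' @param g igraph.
#' @param mother node id.
#' @param f inheritance probability.
#' @return list `graph`, `daughter`, `inherited` (neighbour ids linked).
#' @export
duplicate_node <- function(g, mother, f) {
  stopifnot(mother >= 1, mother <= igraph::vcount(g))
  nb <- as.integer(igraph::neighbors(g, mother))
  inherited <- nb[stats::runif(length(nb)) < f]
  d <- igraph::vcount(g) + 1L
  g <- igraph::add_vertices(g, 1)
  g <- igraph::add_edges(g, rbind(c(mother, inherited),
                                  rep(d, 1 + length(inherited))))
  list(graph = g, daughter = d, inherited = inherited)
}

#' Remove each edge independently with probability r
#'
#' Isolated nodes are retained.
#'
#' @param g igraph.
#' @param r removal probability in \[0, 1).
#' @return list `graph`, `removed` (count).
#' @export
apply_edge_loss <- function(g, r) {
  stopifnot(r >= 0, r < 1)
  m <- igraph::ecount(g)
  if (m == 0 || r == 0) return(list(graph = g, removed = 0L))
  drop <- which(stats::runif(m) < r)
  list(graph = igraph::delete_edges(g, drop), removed = length(drop))
}

#' Simulate network growth by kinetic Monte Carlo
#'
#' Repeats draw-event / apply-event (/ optional edge loss) until the node
#' count reaches `target_nodes`. Event selection is exact: an addition is
#' chosen with probability `pi / R` and node `i` with probability
#' `rate_i / R`, where `R` is the total rate; for the PCM the
#' degree-proportional node choice is realised by sampling a uniform edge
#' endpoint. Waiting times are `-log(u)/R`. The simulated clock accumulates
#' waiting times; termination is by node count.
#'
#' @param params `growth_params`.
#' @param record_log keep the per-event log (time, type, mother, daughter,
#'   inherited-neighbour list).
#' @return object of class `sd_growth`: `params`, `n_nodes`, `edges`
#'   (2-column matrix), `degree`, `time`, `events` (data.frame, or NULL),
#'   `components` (list `sizes`, `edges` per component; exact bookkeeping
#'   when `edge_loss_r = 0`, recomputed otherwise).
#' @export
simulate_growth <- function(params, record_log = TRUE) {
  stopifnot(inherits(params, "growth_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  target <- params$target_nodes
  pcm <- params$model == "pcm"
  delta <- params$delta; pi0 <- params$pi; f <- params$f
  r_loss <- params$edge_loss_r

  cap_n <- target + 2L
  deg <- integer(cap_n)
  comp_id <- integer(cap_n)
  cap_e <- max(64L, 8L * target)
  ea <- integer(cap_e); eb <- integer(cap_e)
  # intrusive incidence lists: edge e owns records 2e-1 (side a) and 2e
  # (side b); inext chains records per node starting at ihead[node];
  # iother[record] caches the opposite endpoint
  ihead <- integer(cap_n)
  inext <- integer(2L * cap_e)
  iother <- integer(2L * cap_e)
  n <- 0L; ne <- 0L; total_deg <- 0L
  n_comp <- 0L
  comp_sizes <- integer(0); comp_edges <- integer(0)
  t_now <- 0
  ev_t <- numeric(0); ev_type <- character(0)
  ev_mother <- integer(0); ev_daughter <- integer(0)
  ev_inh <- list()
  use_adj <- r_loss == 0

  add_edge <- function(u, v) {
    ne <<- ne + 1L
    if (ne > cap_e) {
      cap_e <<- 2L * cap_e
      length(ea) <<- cap_e; length(eb) <<- cap_e
      length(inext) <<- 2L * cap_e; length(iother) <<- 2L * cap_e
    }
    ea[ne] <<- u; eb[ne] <<- v
    deg[u] <<- deg[u] + 1L; deg[v] <<- deg[v] + 1L
    total_deg <<- total_deg + 2L
    if (use_adj) {
      ra <- 2L * ne - 1L; rb <- 2L * ne
      iother[ra] <<- v; iother[rb] <<- u
      inext[ra] <<- ihead[u]; ihead[u] <<- ra
      inext[rb] <<- ihead[v]; ihead[v] <<- rb
    }
  }
  neighbors_of <- function(m) {
    k <- deg[m]
    if (k == 0L) return(integer(0))
    nb <- integer(k); r <- ihead[m]; i <- 0L
    while (r > 0L) {
      i <- i + 1L
      nb[i] <- iother[r]
      r <- inext[r]
    }
    nb
  }

  while (n < target) {
    rate_dup <- if (pcm) delta * total_deg else delta * n
    R <- pi0 + rate_dup
    u1 <- stats::runif(1)
    dt <- -log(1 - stats::runif(1)) / R
    t_now <- t_now + dt
    if (u1 * R < pi0) {
      a <- n + 1L; b <- n + 2L; n <- n + 2L
      n_comp <- n_comp + 1L
      comp_id[a] <- n_comp; comp_id[b] <- n_comp
      comp_sizes[n_comp] <- 2L; comp_edges[n_comp] <- 1L
      add_edge(a, b)
      if (record_log) {
        ev_t <- c(ev_t, t_now); ev_type <- c(ev_type, "add")
        ev_mother <- c(ev_mother, NA_integer_)
        ev_daughter <- c(ev_daughter, a)
        ev_inh <- c(ev_inh, list(integer(0)))
      }
    } else {
      if (pcm) {
        # uniform edge endpoint <=> P(node) proportional to degree
        e <- floor(stats::runif(1) * ne) + 1L
        mother <- if (stats::runif(1) < 0.5) ea[e] else eb[e]
      } else {
        mother <- floor(stats::runif(1) * n) + 1L
      }
      nb <- if (use_adj) neighbors_of(mother)
            else c(eb[seq_len(ne)][ea[seq_len(ne)] == mother],
                   ea[seq_len(ne)][eb[seq_len(ne)] == mother])
      inherited <- if (length(nb)) nb[stats::runif(length(nb)) < f]
                   else integer(0)
      d <- n + 1L; n <- n + 1L
      cid <- comp_id[mother]
      comp_id[d] <- cid
      comp_sizes[cid] <- comp_sizes[cid] + 1L
      comp_edges[cid] <- comp_edges[cid] + 1L + length(inherited)
      add_edge(mother, d)
      for (v in inherited) add_edge(v, d)
      if (record_log) {
        ev_t <- c(ev_t, t_now); ev_type <- c(ev_type, "dup")
        ev_mother <- c(ev_mother, mother); ev_daughter <- c(ev_daughter, d)
        ev_inh <- c(ev_inh, list(inherited))
      }
    }
    if (r_loss > 0 && ne > 0) {
      keep <- stats::runif(ne) >= r_loss
      if (!all(keep)) {
        kept <- which(keep)
        dropped_a <- ea[seq_len(ne)][!keep]; dropped_b <- eb[seq_len(ne)][!keep]
        for (v in c(dropped_a, dropped_b)) deg[v] <- deg[v] - 1L
        total_deg <- total_deg - 2L * sum(!keep)
        ea[seq_along(kept)] <- ea[kept]; eb[seq_along(kept)] <- eb[kept]
        ne <- length(kept)
      }
    }
  }

  edges <- cbind(a = ea[seq_len(ne)], b = eb[seq_len(ne)])
  components <- if (r_loss == 0) {
    list(sizes = comp_sizes[seq_len(n_comp)],
         edges = comp_edges[seq_len(n_comp)])
  } else {
    g <- igraph::make_empty_graph(n, directed = FALSE)
    if (ne) g <- igraph::add_edges(g, t(edges))
    sp <- component_spectrum(g)
    list(sizes = sp$sizes, edges = sp$edges)
  }
  events <- if (record_log) {
    df <- data.frame(time = ev_t, type = ev_type, mother = ev_mother,
                     daughter = ev_daughter, stringsAsFactors = FALSE)
    df$inherited <- ev_inh
    df
  } else NULL
  structure(list(params = params, n_nodes = n, edges = edges,
                 degree = deg[seq_len(n)], time = t_now,
                 events = events, components = components),
            class = "sd_growth")
}

#' @export
print.sd_growth <- function(x, ...) {
  cat(sprintf("%s growth: %d nodes, %d edges, t = %.1f\n",
              toupper(x$params$model), x$n_nodes, nrow(x$edges), x$time))
  invisible(x)
}

#' Convert a simulated growth object to igraph
#'
#' @param sim `sd_growth`.
#' @return igraph (simple; the models never create multi-edges).
#' @export
growth_as_igraph <- function(sim) {
  g <- igraph::make_empty_graph(sim$n_nodes, directed = FALSE)
  if (nrow(sim$edges)) g <- igraph::add_edges(g, t(sim$edges))
  g
}

#' Pool replicate growth simulations
#'
#' Runs `n_reps` simulations with per-replicate seeds derived from a master
#' seed and concatenates their component spectra and degree sequences, the
#' aggregation used for de-noised spectrum and degree distributions.
#'
#' @param params `growth_params` (its `seed` is used as the master seed).
#' @param n_reps number of replicates (the full-scale analyses use 500).
#' @return list `sizes`, `comp_edges` (concatenated over replicates),
#'   `degrees`, `mean_edges_by_size` (data.frame `N`, `mean_E`),
#'   `biggest` (largest component size per replicate), `n_reps`.
#' @export
pool_simulations <- function(params, n_reps = 500) {
  stopifnot(n_reps >= 1)
  if (!is.null(params$seed)) set.seed(params$seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  sizes <- vector("list", n_reps); cedges <- vector("list", n_reps)
  degrees <- vector("list", n_reps); biggest <- integer(n_reps)
  for (i in seq_len(n_reps)) {
    p <- params; p$seed <- rep_seeds[i]
    sim <- simulate_growth(p, record_log = FALSE)
    sizes[[i]] <- sim$components$sizes
    cedges[[i]] <- sim$components$edges
    degrees[[i]] <- sim$degree
    biggest[i] <- max(sim$components$sizes)
  }
  sizes <- unlist(sizes); cedges <- unlist(cedges)
  agg <- stats::aggregate(cedges, by = list(N = sizes), FUN = mean)
  names(agg)[2] <- "mean_E"
  list(sizes = sizes, comp_edges = cedges, degrees = unlist(degrees),
       mean_edges_by_size = agg[order(agg$N), ], biggest = biggest,
       n_reps = n_reps)
}
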
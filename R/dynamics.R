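# Population dynamics and the yearly closed-loop simulation:
# grow -> monitor -> set quota -> perturb quota -> harvest -> remove.

#' One step of discrete logistic growth
#'
#' `N + r * N * (1 - N / K)`, floored at zero. Populations are continuous;
#' no integer rounding is applied.
#'
#' @param N population size(s) before growth (>= 0; vectorized).
#' @param r intrinsic growth rate(s) for the step.
#' @param K carrying capacity (> 0).
#' @return population after growth, >= 0.
#' @export
logistic_step <- function(N, r, K) {
  if (any(K <= 0)) mse_abort("mse_domain_error", "K must be > 0")
  if (any(N < 0)) mse_abort("mse_domain_error", "N must be >= 0")
  pmax(0, N + r * N * (1 - N / K))
}

#' Draw the stochastic variation series for one replicate
#'
#' Each of the four variation sources (growth rate r; monitoring m; quota
#' setting q; harvest implementation h) is modelled as
#' `center + b_i + e_{i,t}`: a replicate-level normal effect `b_i` with
#' variance `variance_partition * sigma^2` plus yearly normal noise with the
#' remaining variance, truncated to the declared bounds (lower bound 0 for
#' the multiplicative factors m, q, h; the species' `r_bounds` for r).
#' Centers are `r_mean` for r and 1 for m, q, h. With all sigmas zero the
#' draws are exactly the centers.
#'
#' @param species an `mse_species`.
#' @param variability `"low"` or `"high"` (selects the sigma per source).
#' @param timeframe number of years to draw.
#' @param variance_partition fraction of each source's variance assigned to
#'   the replicate level (default 0.5).
#' @param seed optional integer seed applied before drawing (the simulator
#'   passes the derived replicate seed).
#' @return list with numeric vectors `r`, `m`, `q`, `h` of length
#'   `timeframe`, each within its truncation bounds.
#' @export
draw_variation <- function(species, variability, timeframe,
                           variance_partition = 0.5, seed = NULL) {
  variability <- match.arg(variability, VARIABILITY_LEVELS)
  if (!is.null(seed)) set.seed(seed)
  draws <- list()
  centers <- c(r = species$r_mean, m = 1, q = 1, h = 1)
  for (src in c("r", "m", "q", "h")) {
    sigma <- species$sd[[src]][[variability]]
    lo <- if (src == "r") species$r_bounds[1] else 0
    hi <- if (src == "r") species$r_bounds[2] else Inf
    if (sigma == 0) {
      draws[[src]] <- rep(min(max(centers[[src]], lo), hi), timeframe)
      next
    }
    b <- stats::rnorm(1, 0, sqrt(variance_partition) * sigma)
    sd_year <- sqrt(1 - variance_partition) * sigma
    draws[[src]] <- rtrunc_norm(timeframe, mean = centers[[src]] + b,
                                sd = sd_year, lower = lo, upper = hi)
  }
  draws
}

# propagate n replicates through T years given pre-drawn noise matrices
# (n x T). Returns matrices plus extinction bookkeeping.
propagate <- function(N0, noise, K, quota_fn, extinction_floor) {
  n <- nrow(noise$r)
  T <- ncol(noise$r)
  N <- N_pre <- N_obs <- Q <- Q_mod <- H <- matrix(0, n, T)
  N_prev <- rep(N0, n)
  ext_year <- rep(NA_integer_, n)
  for (t in seq_len(T)) {
    N_grow <- pmax(0, N_prev + noise$r[, t] * N_prev * (1 - N_prev / K))
    Nhat <- noise$m[, t] * N_grow
    q0 <- quota_fn(Nhat)
    qm <- noise$q[, t] * q0
    h <- pmin(pmax(0, noise$h[, t] * qm), N_grow)
    Npost <- N_grow - h
    dead <- Npost < extinction_floor
    Npost[dead] <- 0
    newly <- dead & is.na(ext_year)
    ext_year[newly] <- t
    N_pre[, t] <- N_grow
    N_obs[, t] <- Nhat
    Q[, t] <- q0
    Q_mod[, t] <- qm
    H[, t] <- h
    N[, t] <- Npost
    N_prev <- Npost
  }
  list(N = N, N_pre = N_pre, N_obs = N_obs, Q = Q, Q_mod = Q_mod, H = H,
       extinct = !is.na(ext_year), extinction_year = ext_year)
}

make_trajectory <- function(sim, i, context, strategy) {
  structure(list(
    years = seq_len(ncol(sim$N)),
    N = sim$N[i, ],
    N_pre = sim$N_pre[i, ],
    N_obs = sim$N_obs[i, ],
    Q = sim$Q[i, ],
    Q_mod = sim$Q_mod[i, ],
    H = sim$H[i, ],
    extinct = sim$extinct[i],
    extinction_year = sim$extinction_year[i],
    context = context$label,
    strategy = strategy_label(strategy)
  ), class = "mse_trajectory")
}

#' @export
print.mse_trajectory <- function(x, ...) {
  cat(sprintf("<mse_trajectory> %s | %s | %d years%s\n",
              x$context, x$strategy, length(x$years),
              if (x$extinct) sprintf(" | extinct in year %d", x$extinction_year) else ""))
  print(utils::head(as.data.frame(x), 5L))
  if (length(x$years) > 5L) cat(sprintf("  ... %d more years\n", length(x$years) - 5L))
  invisible(x)
}

#' @export
as.data.frame.mse_trajectory <- function(x, ...) {
  data.frame(year = x$years, N = x$N, N_pre = x$N_pre, N_obs = x$N_obs,
             Q = x$Q, Q_mod = x$Q_mod, H = x$H)
}

#' Simulate a single replicate trajectory
#'
#' Runs the yearly loop for one replicate: (1) logistic growth with the
#' year's stochastic growth rate; (2) monitoring, multiplying the true
#' population by the monitoring factor; (3) quota setting from the estimate;
#' (4) stakeholder perturbation of the quota; (5) realized harvest, the
#' perturbed quota times the implementation factor, bounded below by 0 and
#' above by the available population; (6) removal. A post-harvest population
#' below the extinction floor is set to 0, absorbing.
#'
#' @param context an `mse_context`.
#' @param strategy an `mse_strategy`.
#' @param config an `mse_config` (supplies timeframe, variance partition,
#'   extinction floor).
#' @param replicate_seed integer seed for this replicate's random stream.
#' @return an `mse_trajectory` with yearly series `N` (true, post-harvest),
#'   `N_pre` (pre-harvest), `N_obs`, `Q`, `Q_mod`, `H`, plus `extinct` and
#'   `extinction_year`.
#' @export
simulate_replicate <- function(context, strategy, config, replicate_seed) {
  ex <- config$experiment
  noise <- draw_variation(context$species, context$variability, ex$timeframe,
                          ex$variance_partition, seed = replicate_seed)
  sim <- propagate(context$N0,
                   lapply(noise, function(v) matrix(v, nrow = 1)),
                   context$species$K, quota_function(strategy),
                   ex$extinction_floor)
  make_trajectory(sim, 1L, context, strategy)
}

#' Simulate all replicates of one (context, strategy) scenario
#'
#' Replicate `i` uses a seed derived deterministically from the master seed,
#' the context label, the strategy label, and `i`; results are therefore
#' independent of execution order and identical across repeated calls.
#'
#' @param context an `mse_context`.
#' @param strategy an `mse_strategy`.
#' @param config an `mse_config`.
#' @param n_replicates optional override of `config$experiment$n_replicates`.
#' @return an `mse_scenario` object: matrices (`n_replicates` x timeframe)
#'   `N`, `N_pre`, `N_obs`, `Q`, `Q_mod`, `H` plus vectors `extinct`,
#'   `extinction_year`. Extract single replicates with [get_trajectory()].
#' @export
simulate_scenario <- function(context, strategy, config, n_replicates = NULL) {
  ex <- config$experiment
  n <- as.integer(n_replicates %||% ex$n_replicates)
  T <- ex$timeframe
  noise <- list(r = matrix(0, n, T), m = matrix(0, n, T),
                q = matrix(0, n, T), h = matrix(0, n, T))
  slab <- strategy_label(strategy)
  for (i in seq_len(n)) {
    seed_i <- hash_seed(ex$master_seed, context$label, slab, i)
    d <- draw_variation(context$species, context$variability, T,
                        ex$variance_partition, seed = seed_i)
    noise$r[i, ] <- d$r; noise$m[i, ] <- d$m
    noise$q[i, ] <- d$q; noise$h[i, ] <- d$h
  }
  sim <- propagate(context$N0, noise, context$species$K,
                   quota_function(strategy), ex$extinction_floor)
  sim$context <- context
  sim$strategy <- strategy
  class(sim) <- "mse_scenario"
  sim
}

#' Extract one replicate's trajectory from a simulated scenario
#'
#' @param scenario an `mse_scenario` from [simulate_scenario()].
#' @param i replicate index.
#' @return an `mse_trajectory`.
#' @export
get_trajectory <- function(scenario, i) {
  make_trajectory(scenario, i, scenario$context, scenario$strategy)
}

#' @export
print.mse_scenario <- function(x, ...) {
  cat(sprintf("<mse_scenario> %s | %s | %d replicates x %d years | %.1f%% extinct\n",
              x$context$label, strategy_label(x$strategy), nrow(x$N), ncol(x$N),
              100 * mean(x$extinct)))
  invisible(x)
}

#' @export
as.data.frame.mse_scenario <- function(x, ...) {
  n <- nrow(x$N); T <- ncol(x$N)
  data.frame(
    context = x$context$label,
    species = x$context$species$name,
    sid = x$context$sid,
    strategy = strategy_label(x$strategy),
    replicate = rep(seq_len(n), times = T),
    year = rep(seq_len(T), each = n),
    N = as.vector(x$N),
    N_pre = as.vector(x$N_pre),
    N_obs = as.vector(x$N_obs),
    Q = as.vector(x$Q),
    Q_mod = as.vector(x$Q_mod),
    H = as.vector(x$H)
  )
}
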
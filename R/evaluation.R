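# Sustainability evaluation: ten individual metrics per replicate,
# context-relative standardization to 0-100, and six composite sets.

#' Names of the ten individual sustainability metrics
#'
#' All metrics are oriented so that higher values are more desirable:
#' `persistence` (0/1, no extinction over the timeframe); year counts
#' `stable_population` (between the low and high thresholds),
#' `above_quasi_extinct`, `above_low`, `below_high`, `below_overabundant`;
#' `harvest_mean` (mean yearly harvest); `harvest_minimum` (smallest yearly
#' harvest); `harvest_non_zeros` (years with non-zero harvest);
#' `harvest_consistency` (0 minus the standard deviation of yearly harvests).
#'
#' @return character vector of length 10.
#' @export
metric_names <- function() {
  c("persistence", "stable_population", "above_quasi_extinct", "above_low",
    "below_high", "below_overabundant", "harvest_mean", "harvest_minimum",
    "harvest_non_zeros", "harvest_consistency")
}

#' The six composite metric sets
#'
#' Named subsets of the ten individual metrics representing alternative
#' stakeholder evaluation perspectives, from the two-metric classic
#' harvest view (persistence + mean harvest) to the complete set of all ten.
#' Persistence is a member of every set.
#'
#' @return named list of character vectors.
#' @export
composite_sets <- function() {
  list(
    classic_harv = c("persistence", "harvest_mean"),
    classic_pop_harv = c("persistence", "stable_population", "harvest_mean"),
    population_focus = c("persistence", "above_quasi_extinct", "above_low",
                         "stable_population", "below_high", "below_overabundant"),
    harvest_focus = c("persistence", "harvest_mean", "harvest_minimum",
                      "harvest_non_zeros", "harvest_consistency"),
    complete_small_game = c("persistence", "above_quasi_extinct", "above_low",
                            "harvest_mean", "harvest_minimum",
                            "harvest_non_zeros", "harvest_consistency"),
    complete = metric_names()
  )
}

raw_metrics_from_series <- function(N, H, extinct, species) {
  c(
    persistence = as.numeric(!extinct),
    stable_population = sum(N > species$threshold_low & N < species$threshold_high),
    above_quasi_extinct = sum(N > species$threshold_quasi_extinct),
    above_low = sum(N > species$threshold_low),
    below_high = sum(N < species$threshold_high),
    below_overabundant = sum(N < species$threshold_overabundant),
    harvest_mean = mean(H),
    harvest_minimum = min(H),
    harvest_non_zeros = sum(H > 0),
    harvest_consistency = if (length(H) > 1L) -stats::sd(H) else 0
  )
}

#' Compute the ten raw sustainability metrics for one trajectory
#'
#' Population-based metrics count years (strict inequalities in the stated
#' direction, ties not counting) of the recorded population series against
#' the species' critical thresholds; by default the post-harvest series is
#' used (`config$experiment$evaluate_on = "pre_harvest"` switches to the
#' pre-harvest series). Harvest metrics are computed on the realized harvest
#' series; persistence from the extinction flag.
#'
#' @param trajectory an `mse_trajectory`.
#' @param species the `mse_species` the trajectory was simulated under.
#' @param config an `mse_config` (only `evaluate_on` is consulted); omit for
#'   the post-harvest default.
#' @return named numeric vector over [metric_names()].
#' @export
compute_raw_metrics <- function(trajectory, species, config = NULL) {
  on <- (config$experiment$evaluate_on %||% "post_harvest")
  N <- if (on == "pre_harvest") trajectory$N_pre else trajectory$N
  raw_metrics_from_series(N, trajectory$H, trajectory$extinct, species)
}

#' Raw metrics for every replicate of a simulated scenario
#'
#' Applies [compute_raw_metrics()] to each replicate of an `mse_scenario`.
#'
#' @param scenario an `mse_scenario` from [simulate_scenario()].
#' @param config an `mse_config` (only `evaluate_on` is consulted).
#' @return numeric matrix, replicates x [metric_names()].
#' @export
scenario_raw_metrics <- function(scenario, config = NULL) {
  on <- (config$experiment$evaluate_on %||% "post_harvest")
  Nmat <- if (on == "pre_harvest") scenario$N_pre else scenario$N
  sp <- scenario$context$species
  n <- nrow(Nmat)
  out <- matrix(0, n, 10L, dimnames = list(NULL, metric_names()))
  for (i in seq_len(n)) {
    out[i, ] <- raw_metrics_from_series(Nmat[i, ], scenario$H[i, ],
                                        scenario$extinct[i], sp)
  }
  out
}

#' Resolve standardization bounds for one environmental context
#'
#' Bounds map each metric's worst value to 0 and its best to 100, per
#' environmental context. Persistence and the year-count metrics have
#' absolute ideals (0/1 and 0/timeframe years); the harvest volume metrics
#' (`harvest_mean`, `harvest_minimum`) are bounded above by the largest
#' value observed anywhere in the context's ensemble (all replications of
#' all decision variables), and `harvest_consistency` is bounded below by
#' minus the largest observed harvest standard deviation.
#'
#' @param raw matrix of raw metrics (rows = replicates pooled over every
#'   strategy and parameter simulated for the context; columns =
#'   [metric_names()]).
#' @param timeframe the experiment timeframe in years.
#' @return object of class `mse_bounds`: named list of `c(worst, best)`
#'   pairs.
#' @export
resolve_bounds <- function(raw, timeframe) {
  if (is.null(dim(raw)) || nrow(raw) == 0L)
    mse_abort("mse_domain_error", "cannot resolve bounds from an empty ensemble")
  b <- list(persistence = c(0, 1))
  for (m in c("stable_population", "above_quasi_extinct", "above_low",
              "below_high", "below_overabundant", "harvest_non_zeros"))
    b[[m]] <- c(0, timeframe)
  b$harvest_mean <- c(0, max(raw[, "harvest_mean"]))
  b$harvest_minimum <- c(0, max(raw[, "harvest_minimum"]))
  b$harvest_consistency <- c(min(raw[, "harvest_consistency"]), 0)
  structure(b, class = "mse_bounds")
}

#' Standardize raw metrics to the 0-100 scale
#'
#' Linear map `100 * (value - worst) / (best - worst)`, clipped to
#' \[0, 100\] (the clip guards floating-point overshoot only; by
#' construction values fall inside the bounds). A metric with degenerate
#' bounds (best equal to worst, e.g. a context in which no strategy ever
#' harvests) scores 100 where the value equals the ideal pole and 0
#' elsewhere; a warning is issued.
#'
#' @param raw named vector or matrix of raw metrics (columns =
#'   [metric_names()]).
#' @param bounds an `mse_bounds` from [resolve_bounds()].
#' @return standardized values with the same shape as `raw`.
#' @export
standardize_metrics <- function(raw, bounds) {
  vec <- is.null(dim(raw))
  if (vec) raw <- matrix(raw, nrow = 1L, dimnames = list(NULL, names(raw)))
  out <- raw
  degenerate <- character(0)
  for (m in metric_names()) {
    w <- bounds[[m]][1]; b <- bounds[[m]][2]
    if (b == w) {
      degenerate <- c(degenerate, m)
      out[, m] <- ifelse(raw[, m] == b, 100, 0)
    } else {
      out[, m] <- pmin(100, pmax(0, 100 * (raw[, m] - w) / (b - w)))
    }
  }
  if (length(degenerate))
    warning(sprintf("degenerate standardization bounds for: %s",
                    paste(degenerate, collapse = ", ")), call. = FALSE)
  if (vec) out[1, ] else out
}

#' Per-replicate composite scores for the requested metric sets
#'
#' The composite score of a replicate is the unweighted mean of the
#' standardized member metrics; scenario-level summaries (mean over
#' replicates, sd, quartiles) are computed from the per-replicate scores.
#'
#' @param standardized matrix of standardized metrics (replicates x metrics).
#' @param sets character vector of composite set names (default all six).
#' @return list with `replicate` (replicates x sets matrix of per-replicate
#'   composites) and `summary` (data.frame with one row per set: mean, sd,
#'   quartiles).
#' @export
composite_scores <- function(standardized, sets = names(composite_sets())) {
  defs <- composite_sets()
  bad <- setdiff(sets, names(defs))
  if (length(bad))
    mse_abort("mse_schema_error", "unknown composite set(s): %s", paste(bad, collapse = ", "))
  if (is.null(dim(standardized)))
    standardized <- matrix(standardized, nrow = 1L,
                           dimnames = list(NULL, names(standardized)))
  rep_scores <- sapply(sets, function(s)
    rowMeans(standardized[, defs[[s]], drop = FALSE]))
  if (is.null(dim(rep_scores)))
    rep_scores <- matrix(rep_scores, nrow = 1L, dimnames = list(NULL, sets))
  qs <- apply(rep_scores, 2L, stats::quantile, probs = c(0.25, 0.5, 0.75),
              names = FALSE)
  summary <- data.frame(
    set = sets,
    score = colMeans(rep_scores),
    score_sd = apply(rep_scores, 2L, stats::sd),
    q25 = qs[1, ], q50 = qs[2, ], q75 = qs[3, ],
    row.names = NULL
  )
  list(replicate = rep_scores, summary = summary)
}
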
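# Configuration layer: species profiles, environmental contexts,
# experiment settings, and deterministic enumeration of the factorial grids.

VARIABILITY_LEVELS <- c("low", "high")
START_SCENARIOS <- c("moderate", "quasi_extinction", "overabundance")

#' Construct and validate a species profile
#'
#' A species profile bundles the life-history parameters (intrinsic growth
#' rate, carrying capacity), the four critical population thresholds used by
#' the evaluation metrics, and the magnitudes of the four variation sources
#' (growth rate r, monitoring m, quota setting q, harvest implementation h)
#' at the low and high variability levels. The moderate population size is
#' defined as the midpoint of the low and high critical thresholds.
#'
#' @param name species label.
#' @param r_mean mean intrinsic yearly growth rate (per year, > 0).
#' @param K carrying capacity (individuals, > 0).
#' @param thresholds named list/vector with elements `quasi_extinct`, `low`,
#'   `high`, `overabundant` (individuals), ordered
#'   `0 < quasi_extinct <= low < high <= overabundant`.
#' @param sd named list with elements `r`, `m`, `q`, `h`, each a named
#'   list/vector with `low` and `high` standard deviations (`low <= high`).
#'   `r` variation is additive around `r_mean`; `m`, `q`, `h` are
#'   multiplicative factors centred on 1.
#' @param r_bounds length-2 truncation bounds for stochastic growth-rate
#'   draws; default `c(-r_mean, 2 * r_mean)`.
#' @return an object of class `mse_species` with derived field
#'   `moderate_size = (low + high) / 2`.
#' @export
species_profile <- function(name, r_mean, K, thresholds, sd,
                            r_bounds = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    mse_abort("mse_schema_error", "species 'name' must be a non-empty string")
  num1 <- function(x, field) {
    if (is.null(x) || !is.numeric(x) || length(x) != 1L || is.na(x))
      mse_abort("mse_schema_error", "species '%s': field '%s' must be a single number",
                name, field)
    as.numeric(x)
  }
  r_mean <- num1(r_mean, "r_mean")
  K <- num1(K, "K")
  th <- lapply(c("quasi_extinct", "low", "high", "overabundant"),
               function(f) num1(thresholds[[f]], paste0("thresholds$", f)))
  names(th) <- c("quasi_extinct", "low", "high", "overabundant")
  if (r_mean <= 0) mse_abort("mse_invariant_error", "species '%s': r_mean must be > 0", name)
  if (K <= 0) mse_abort("mse_invariant_error", "species '%s': K must be > 0", name)
  if (!(0 < th$quasi_extinct))
    mse_abort("mse_invariant_error", "species '%s': threshold_quasi_extinct must be > 0", name)
  if (!(th$quasi_extinct <= th$low))
    mse_abort("mse_invariant_error",
              "species '%s': threshold_quasi_extinct (%g) must be <= threshold_low (%g)",
              name, th$quasi_extinct, th$low)
  if (!(th$low < th$high))
    mse_abort("mse_invariant_error",
              "species '%s': threshold_low (%g) must be < threshold_high (%g)",
              name, th$low, th$high)
  if (!(th$high <= th$overabundant))
    mse_abort("mse_invariant_error",
              "species '%s': threshold_high (%g) must be <= threshold_overabundant (%g)",
              name, th$high, th$overabundant)
  sds <- list()
  for (src in c("r", "m", "q", "h")) {
    lo <- num1(sd[[src]][["low"]], sprintf("sd$%s$low", src))
    hi <- num1(sd[[src]][["high"]], sprintf("sd$%s$high", src))
    if (lo < 0 || hi < 0)
      mse_abort("mse_invariant_error", "species '%s': sd$%s must be >= 0", name, src)
    if (lo > hi)
      mse_abort("mse_invariant_error",
                "species '%s': sd$%s$low (%g) must be <= sd$%s$high (%g)",
                name, src, lo, src, hi)
    sds[[src]] <- c(low = lo, high = hi)
  }
  if (is.null(r_bounds)) r_bounds <- c(-r_mean, 2 * r_mean)
  if (length(r_bounds) != 2L || r_bounds[1] > r_bounds[2])
    mse_abort("mse_invariant_error", "species '%s': r_bounds must be c(lower, upper)", name)
  structure(list(
    name = name,
    r_mean = r_mean,
    K = K,
    threshold_quasi_extinct = th$quasi_extinct,
    threshold_low = th$low,
    threshold_high = th$high,
    threshold_overabundant = th$overabundant,
    moderate_size = (th$low + th$high) / 2,
    sd = sds,
    r_bounds = as.numeric(r_bounds)
  ), class = "mse_species")
}

#' @export
print.mse_species <- function(x, ...) {
  cat(sprintf("<mse_species> %s: r = %g, K = %g\n", x$name, x$r_mean, x$K))
  cat(sprintf("  thresholds: quasi-extinct %g | low %g | high %g | overabundant %g (moderate %g)\n",
              x$threshold_quasi_extinct, x$threshold_low, x$threshold_high,
              x$threshold_overabundant, x$moderate_size))
  invisible(x)
}

#' Construct an environmental context
#'
#' An environmental context couples a species with a variability level (all
#' four variation sources low, or all high) and a starting-population
#' scenario. The scenario identifier (SID, 1-6) codes variability x start:
#' moderate start is SID 1 (low) / 2 (high), quasi-extinction 3/4,
#' overabundance 5/6.
#'
#' @param species an `mse_species` profile.
#' @param variability `"low"` or `"high"`.
#' @param start_scenario `"moderate"`, `"quasi_extinction"` or
#'   `"overabundance"`; resolves the starting population to the species'
#'   moderate size, quasi-extinction threshold, or overabundance threshold.
#' @return an object of class `mse_context` with fields `sid` and `N0`.
#' @export
environmental_context <- function(species, variability, start_scenario) {
  if (!inherits(species, "mse_species"))
    mse_abort("mse_schema_error", "'species' must be an mse_species profile")
  variability <- match.arg(variability, VARIABILITY_LEVELS)
  start_scenario <- match.arg(start_scenario, START_SCENARIOS)
  sid <- (match(start_scenario, START_SCENARIOS) - 1L) * 2L +
    match(variability, VARIABILITY_LEVELS)
  N0 <- switch(start_scenario,
    moderate = species$moderate_size,
    quasi_extinction = species$threshold_quasi_extinct,
    overabundance = species$threshold_overabundant
  )
  structure(list(
    species = species,
    variability = variability,
    start_scenario = start_scenario,
    sid = sid,
    N0 = N0,
    label = sprintf("%s_sid%d", species$name, sid)
  ), class = "mse_context")
}

#' @export
print.mse_context <- function(x, ...) {
  cat(sprintf("<mse_context> %s (SID %d): %s variability, %s start (N0 = %g)\n",
              x$species$name, x$sid, x$variability, x$start_scenario, x$N0))
  invisible(x)
}

default_experiment <- function() {
  list(
    timeframe = 20L,
    n_replicates = 1000L,
    master_seed = 1L,
    variance_partition = 0.5,
    extinction_floor = 1,
    evaluate_on = "post_harvest",
    evaluation_sets = names(composite_sets()),
    variability_levels = VARIABILITY_LEVELS,
    start_scenarios = START_SCENARIOS
  )
}

default_grids <- function() {
  list(
    strategies = c("no_harvest", "constant", "proportional", "threshold_proportional"),
    constant = list(min = 0.01, max = 1.00, step = 0.01),
    proportional = list(min = 0.01, max = 1.00, step = 0.01),
    threshold_proportional = list(
      proportion = list(min = 0.01, max = 1.00, step = 0.01),
      threshold = list(step = 0.01)
    )
  )
}

validate_experiment <- function(ex) {
  if (ex$timeframe < 1) mse_abort("mse_invariant_error", "experiment$timeframe must be >= 1")
  if (ex$n_replicates < 1) mse_abort("mse_invariant_error", "experiment$n_replicates must be >= 1")
  if (ex$variance_partition < 0 || ex$variance_partition > 1)
    mse_abort("mse_invariant_error", "experiment$variance_partition must be in [0, 1]")
  if (!ex$evaluate_on %in% c("post_harvest", "pre_harvest"))
    mse_abort("mse_schema_error", "experiment$evaluate_on must be 'post_harvest' or 'pre_harvest'")
  bad <- setdiff(ex$evaluation_sets, names(composite_sets()))
  if (length(bad))
    mse_abort("mse_schema_error", "unknown evaluation set(s): %s", paste(bad, collapse = ", "))
  if (length(ex$variability_levels) < 1 ||
      length(setdiff(ex$variability_levels, VARIABILITY_LEVELS)))
    mse_abort("mse_schema_error",
              "experiment$variability_levels must be a non-empty subset of {low, high}")
  if (length(ex$start_scenarios) < 1 ||
      length(setdiff(ex$start_scenarios, START_SCENARIOS)))
    mse_abort("mse_schema_error",
              "experiment$start_scenarios must be a non-empty subset of {moderate, quasi_extinction, overabundance}")
  ex
}

validate_range <- function(g, what) {
  for (f in c("min", "max", "step"))
    if (is.null(g[[f]]) || !is.numeric(g[[f]]))
      mse_abort("mse_schema_error", "grid '%s': field '%s' must be numeric", what, f)
  if (g$step <= 0) mse_abort("mse_invariant_error", "grid '%s': step must be > 0", what)
  if (g$min > g$max) mse_abort("mse_invariant_error", "grid '%s': min must be <= max", what)
  g
}

#' Assemble a full experiment configuration
#'
#' @param species list of [species_profile()] objects (order is preserved and
#'   determines context ordering).
#' @param experiment named list overriding the experiment defaults
#'   (`timeframe` 20, `n_replicates` 1000, `master_seed` 1,
#'   `variance_partition` 0.5, `extinction_floor` 1,
#'   `evaluate_on` "post_harvest", `evaluation_sets` all six).
#' @param grids named list overriding the decision-grid defaults; constants
#'   and thresholds are expressed as fractions of the species' moderate size,
#'   proportions as absolute fractions.
#' @return an object of class `mse_config`.
#' @export
mse_config <- function(species, experiment = list(), grids = list()) {
  if (!length(species)) mse_abort("mse_schema_error", "at least one species profile is required")
  species <- lapply(species, function(s) {
    if (!inherits(s, "mse_species"))
      mse_abort("mse_schema_error", "every element of 'species' must be an mse_species")
    s
  })
  names(species) <- vapply(species, `[[`, character(1), "name")
  if (anyDuplicated(names(species)))
    mse_abort("mse_invariant_error", "species names must be unique")
  ex <- utils::modifyList(default_experiment(), experiment)
  ex$timeframe <- as.integer(ex$timeframe)
  ex$n_replicates <- as.integer(ex$n_replicates)
  ex$master_seed <- as.integer(ex$master_seed)
  ex <- validate_experiment(ex)
  gr <- utils::modifyList(default_grids(), grids)
  known <- c("no_harvest", "constant", "proportional", "threshold_proportional")
  bad <- setdiff(gr$strategies, known)
  if (length(bad))
    mse_abort("mse_schema_error", "unknown strategy kind(s): %s", paste(bad, collapse = ", "))
  if ("constant" %in% gr$strategies) validate_range(gr$constant, "constant")
  if ("proportional" %in% gr$strategies) validate_range(gr$proportional, "proportional")
  if ("threshold_proportional" %in% gr$strategies) {
    validate_range(gr$threshold_proportional$proportion, "threshold_proportional$proportion")
    if (is.null(gr$threshold_proportional$threshold$step) ||
        gr$threshold_proportional$threshold$step <= 0)
      mse_abort("mse_invariant_error", "grid 'threshold_proportional$threshold': step must be > 0")
  }
  structure(list(species = species, experiment = ex, grids = gr),
            class = "mse_config")
}

#' @export
print.mse_config <- function(x, ...) {
  cat(sprintf("<mse_config> %d species, T = %d years, %d replicates, master seed %d\n",
              length(x$species), x$experiment$timeframe,
              x$experiment$n_replicates, x$experiment$master_seed))
  for (s in x$species) print(s)
  ctx <- build_environmental_grid(x)
  sizes <- vapply(x$species, function(s) length(build_decision_grid(x, s)), integer(1))
  cat(sprintf("  environmental contexts: %d; decision specs per species: %s\n",
              length(ctx), paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

species_from_list <- function(sp) {
  for (f in c("name", "r_mean", "K", "thresholds", "sd"))
    if (is.null(sp[[f]]))
      mse_abort("mse_schema_error", "species entry is missing required field '%s'", f)
  species_profile(sp$name, sp$r_mean, sp$K, sp$thresholds, sp$sd,
                  r_bounds = sp$r_bounds)
}

#' Load an experiment configuration from a YAML file
#'
#' The file may define `species` (a list of profiles), `experiment` settings
#' and `grids`; omitted optional fields take the documented defaults. Every
#' validation failure names the offending field and is raised with a
#' distinct condition class (`mse_missing_file_error`, `mse_schema_error`,
#' `mse_invariant_error`).
#'
#' @param path path to a YAML configuration file.
#' @return an `mse_config` object.
#' @seealso [default_config()] for the shipped three-species configuration.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    mse_abort("mse_missing_file_error", "config file not found: %s", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    mse_abort("mse_schema_error", "config file does not parse as YAML: %s",
              conditionMessage(e)))
  if (is.null(raw$species))
    mse_abort("mse_schema_error", "config must define at least one entry under 'species'")
  species <- lapply(raw$species, species_from_list)
  mse_config(species,
             experiment = raw$experiment %||% list(),
             grids = raw$grids %||% list())
}

#' Load the shipped default three-species configuration
#'
#' Moose, roe deer and willow ptarmigan profiles spanning a slow-fast
#' life-history gradient. Moderate population sizes are 600, 6950 and 17500
#' individuals respectively; the remaining life-history and variation values
#' are documented placeholders consistent with the slow-fast ordering (see
#' the configuration file itself and the methods vignette) and are meant to
#' be overridden with case-specific values.
#'
#' @return an `mse_config` object.
#' @export
default_config <- function() {
  path <- system.file("extdata", "default_config.yaml", package = "harvestMSE")
  if (!nzchar(path)) # during development, before installation
    path <- file.path("inst", "extdata", "default_config.yaml")
  load_config(path)
}

#' Enumerate the environmental-context grid
#'
#' Full cross product of configured species x variability levels x starting
#' population scenarios, in deterministic order: species as configured, then
#' SID ascending.
#'
#' @param config an `mse_config`.
#' @return list of `mse_context` objects.
#' @export
build_environmental_grid <- function(config) {
  ex <- config$experiment
  starts <- intersect(START_SCENARIOS, ex$start_scenarios)
  vars <- intersect(VARIABILITY_LEVELS, ex$variability_levels)
  out <- list()
  for (sp in config$species) {
    for (start in starts) {
      for (v in vars) {
        out[[length(out) + 1L]] <- environmental_context(sp, v, start)
      }
    }
  }
  # nesting above already yields SID-ascending order within each species
  out
}

#' Enumerate the decision-variable grid for one species
#'
#' One no-harvest baseline; constants at configured increments of the
#' species' moderate population size; proportions at configured absolute
#' increments; threshold-proportional as the cross product of the proportion
#' grid with thresholds running from the quasi-extinction threshold to the
#' moderate size in increments of the configured fraction of the moderate
#' size. Ordering is deterministic: strategy kind, then ascending parameters
#' (thresholds nested within proportions).
#'
#' @param config an `mse_config`.
#' @param species an `mse_species` (one of `config$species`).
#' @return list of `mse_strategy` specs.
#' @export
build_decision_grid <- function(config, species) {
  gr <- config$grids
  specs <- list()
  add <- function(s) specs[[length(specs) + 1L]] <<- s
  if ("no_harvest" %in% gr$strategies) add(harvest_strategy("no_harvest"))
  if ("constant" %in% gr$strategies) {
    fr <- seq_grid(gr$constant$min, gr$constant$max, gr$constant$step)
    if (!length(fr)) mse_abort("mse_invariant_error", "constant grid is empty")
    for (f in fr) add(harvest_strategy("constant",
                                       constant = f * species$moderate_size,
                                       fraction = f))
  }
  if ("proportional" %in% gr$strategies) {
    pr <- seq_grid(gr$proportional$min, gr$proportional$max, gr$proportional$step)
    if (!length(pr)) mse_abort("mse_invariant_error", "proportional grid is empty")
    for (p in pr) add(harvest_strategy("proportional", proportion = p))
  }
  if ("threshold_proportional" %in% gr$strategies) {
    tp <- gr$threshold_proportional
    pr <- seq_grid(tp$proportion$min, tp$proportion$max, tp$proportion$step)
    step_ind <- tp$threshold$step * species$moderate_size
    thr <- seq_grid(species$threshold_quasi_extinct, species$moderate_size, step_ind)
    if (!length(pr) || !length(thr))
      mse_abort("mse_invariant_error", "threshold_proportional grid is empty")
    for (p in pr) for (th in thr)
      add(harvest_strategy("threshold_proportional", proportion = p,
                           threshold = th,
                           threshold_fraction = th / species$moderate_size))
  }
  specs
}
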
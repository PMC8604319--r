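# Shared fixtures: all built in code at test time.

# a mid-sized test species with round-number thresholds
test_species <- function(sd_all = 0.1, name = "testium") {
  species_profile(
    name = name, r_mean = 0.3, K = 1200,
    thresholds = list(quasi_extinct = 100, low = 400, high = 800,
                      overabundant = 1100),
    sd = list(r = list(low = sd_all / 2, high = sd_all),
              m = list(low = sd_all / 2, high = sd_all),
              q = list(low = sd_all / 2, high = sd_all),
              h = list(low = sd_all / 2, high = sd_all))
  )
}

# single-species config; sd_all = 0 gives a fully deterministic system
test_config <- function(sd_all = 0, n_replicates = 3, timeframe = 20,
                        master_seed = 7, grids = list(), experiment = list()) {
  mse_config(
    species = list(test_species(sd_all)),
    experiment = utils::modifyList(list(
      timeframe = timeframe, n_replicates = n_replicates,
      master_seed = master_seed
    ), experiment),
    grids = grids
  )
}

# tiny factorial config: 1 context, 2 strategy kinds x 3 parameter values,
# 2 evaluation sets, 10 replicates
toy_factorial_config <- function(master_seed = 11, n_replicates = 10) {
  test_config(
    sd_all = 0.1, n_replicates = n_replicates, timeframe = 10,
    master_seed = master_seed,
    experiment = list(evaluation_sets = c("classic_harv", "complete"),
                      variability_levels = "low",
                      start_scenarios = "moderate"),
    grids = list(strategies = c("constant", "proportional"),
                 constant = list(min = 0.1, max = 0.3, step = 0.1),
                 proportional = list(min = 0.1, max = 0.3, step = 0.1))
  )
}

# the hand-countable five-year trajectory (matches the shipped fixture)
toy_trajectory <- function() {
  structure(list(
    years = 1:5,
    N = c(500, 450, 380, 0, 0),
    N_pre = c(500, 450, 380, 0, 0),
    N_obs = c(500, 450, 380, 0, 0),
    Q = c(50, 60, 40, 0, 0),
    Q_mod = c(50, 60, 40, 0, 0),
    H = c(50, 60, 40, 0, 0),
    extinct = TRUE,
    extinction_year = 4L,
    context = "fixture", strategy = "fixture"
  ), class = "mse_trajectory")
}
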
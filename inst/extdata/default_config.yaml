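# Default three-species configuration: moose, roe deer, willow ptarmigan,
# spanning a slow-fast life-history gradient.
#
# The moderate population sizes implied by the thresholds (midpoint of the
# low and high critical thresholds) are the published values: moose 600,
# roe deer 6950, ptarmigan 17500 individuals. All OTHER species values
# (r_mean, K, the four thresholds themselves, and the variation magnitudes)
# are PLACEHOLDERS: plausible values chosen to respect the slow-fast
# ordering (moose lowest growth rate, carrying capacity, variation and
# thresholds; ptarmigan highest). Replace them with case-specific estimates
# for any substantive application; every field here can be overridden.
#
# Units: individuals and years. Constants and thresholds in the grids are
# fractions of each species' moderate population size; proportions are
# absolute fractions. Variation sd's: r is additive around r_mean; m, q, h
# are multiplicative factors centred on 1.

experiment:
  timeframe: 20
  n_replicates: 1000
  master_seed: 1
  variance_partition: 0.5   # share of each variance at the replicate level
  extinction_floor: 1       # individuals; below this the population is 0
  evaluate_on: post_harvest
  evaluation_sets: [classic_harv, classic_pop_harv, population_focus,
                    harvest_focus, complete_small_game, complete]

grids:
  strategies: [no_harvest, constant, proportional, threshold_proportional]
  constant:     {min: 0.01, max: 1.00, step: 0.01}
  proportional: {min: 0.01, max: 1.00, step: 0.01}
  threshold_proportional:
    proportion: {min: 0.01, max: 1.00, step: 0.01}
    threshold:  {step: 0.01}   # quasi-extinction -> moderate size

species:
  - name: moose
    r_mean: 0.25
    K: 1500
    thresholds: {quasi_extinct: 100, low: 400, high: 800, overabundant: 1200}
    sd:
      r: {low: 0.05, high: 0.10}
      m: {low: 0.05, high: 0.15}
      q: {low: 0.05, high: 0.10}
      h: {low: 0.05, high: 0.10}
  - name: roe_deer
    r_mean: 0.45
    K: 17000
    thresholds: {quasi_extinct: 1000, low: 4400, high: 9500, overabundant: 14000}
    sd:
      r: {low: 0.10, high: 0.20}
      m: {low: 0.10, high: 0.20}
      q: {low: 0.05, high: 0.15}
      h: {low: 0.05, high: 0.15}
  - name: ptarmigan
    r_mean: 0.90
    K: 45000
    thresholds: {quasi_extinct: 2000, low: 10000, high: 25000, overabundant: 35000}
    sd:
      r: {low: 0.20, high: 0.40}
      m: {low: 0.15, high: 0.30}
      q: {low: 0.10, high: 0.20}
      h: {low: 0.10, high: 0.20}
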
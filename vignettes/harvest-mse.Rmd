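---
title: "Methods: a semi-complex MSE framework for wildlife harvest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a semi-complex MSE framework for wildlife harvest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(harvestMSE)
```

## The system being simulated

`harvestMSE` simulates a single closed, unstructured wildlife population
under yearly harvest management, as a loop of five coupled components:
resource dynamics, monitoring, quota decision, harvest implementation, and
(after the simulation) evaluation. The intent is deliberately *semi-complex*:
richer than a one-equation yield model — monitoring error, stakeholder
influence on quotas, and implementation error are all present — but far
simpler than a tailored case-study model, so that the same machinery can be
run factorially across species, contexts and control rules and the results
compared like-for-like.

### Resource dynamics

The population grows by one discrete logistic step per year,

$$N^{grow}_t = N_{t-1} + r_t\,N_{t-1}\left(1 - \frac{N_{t-1}}{K}\right),$$

floored at zero. Populations are continuous (no integer rounding): the
logistic model is itself continuous, and rounding would introduce artefacts
at the small population sizes where the evaluation thresholds live.
"Extinction" is therefore defined by a floor: when the post-harvest
population drops below `extinction_floor` (default 1 individual) it is set
to 0, which is absorbing. The growth rate `r_t` is stochastic (below); `K`
is fixed per species.

### Within-year ordering

The yearly order is fixed as *grow → observe → decide → perturb → harvest →
remove*:

1. `N_grow` from the logistic step;
2. monitoring estimate `N_obs = m_t · N_grow`;
3. initial quota `Q_t` from the harvest control rule applied to `N_obs`;
4. perturbed quota `Q'_t = q_t · Q_t` (stakeholder influence on quota
   setting);
5. realized harvest `H_t = min(max(0, h_t · Q'_t), N_grow)` — implementation
   error, never negative and never more than the animals available;
6. removal: `N_t = N_grow − H_t`.

This ordering follows the natural reading of the management cycle
(monitoring informs the decision made on this year's grown population); both
the pre-harvest (`N_pre`) and post-harvest (`N`) series are recorded, and
evaluation uses the post-harvest series by default
(`experiment$evaluate_on = "pre_harvest"` switches).

### Stochasticity and uncertainty

Four variation sources: growth rate `r` (additive around the species mean),
and multiplicative factors `m`, `q`, `h` centred on 1 for monitoring, quota
setting and implementation. Each source has a normal law whose standard
deviation is set by the context's variability level (low/high), and its
variance is *partitioned* between a replicate-level effect `b_i` (drawn once
per replicate — parameter uncertainty that persists over the timeframe) and
yearly noise `e_{i,t}` (temporal stochasticity):

$$x_{i,t} = \mathrm{center} + b_i + e_{i,t},\qquad
b_i \sim N(0, v\sigma^2),\; e_{i,t} \sim N(0, (1-v)\sigma^2),$$

with `variance_partition` `v` defaulting to 0.5 — an equal split, chosen as
the neutral default in the absence of a stated allocation. Draws are
truncated: `m`, `q`, `h` at 0 below (a survey cannot report a negative
population; a harvest cannot be negative) with no upper bound, and `r` to
`r_bounds`, default `[-r_mean, 2·r_mean]`, preventing pathological crashes
or explosions while allowing occasional negative growth years. Yearly draws
are taken from a truncated normal conditional on the replicate effect
(inverse-CDF sampling; exact), so every realized factor respects its bounds;
with `σ = 0` every draw equals its center exactly, which is what makes the
zero-variability configurations bitwise reproducible.

### Harvest control rules

Four strategy kinds: *no harvest* (baseline), *constant* (`Q = c`),
*proportional* (`Q = p·N_obs`), *threshold-proportional* (`Q = p·N_obs` if
`N_obs > T`, else 0). Two deliberate readings are fixed here:

* the threshold rule harvests the proportion of the **whole** estimate once
  the threshold is exceeded, not of the surplus above it (a surplus variant
  exists behind `surplus = TRUE` but is not the default, and is not part of
  the factorial);
* the threshold comparison is strict (`N_obs > T`); with continuous
  populations the tie case has probability zero and the choice is
  immaterial, but it is documented and tested.

Strategy and parameters are held fixed over a simulation's 20 years —
realized harvests still vary through `q` and `h` — matching the
"commit to a rule, then evaluate" framing of strategy evaluation.

## Contexts and decision grids

An environmental context is species × variability (low/high, applied to all
four sources together) × starting population (moderate = midpoint of the low
and high critical thresholds; quasi-extinction; overabundance — the latter
two start the population exactly at the corresponding threshold). SID codes
1–6 enumerate variability × start within a species; three species give the
18-context factorial.

Parameter grids are species-portable by construction: constants and
thresholds are configured as fractions of the species' *moderate* population
size, proportions as absolute fractions, all in 1% increments by default.
Thresholds range from the quasi-extinction threshold up to the moderate
size. Grid enumeration is deterministic (strategy kind, then ascending
parameters, thresholds nested within proportions), which matters because
every (context, strategy, replicate) cell derives its random seed from its
identity — results are independent of execution order, parallelization, or
which subset of cells is re-run.

### Species profiles

Only the moderate population sizes of the three species are fixed by
published values (moose 600, roe deer 6950, willow ptarmigan 17500). The
remaining profile values in `inst/extdata/default_config.yaml` — growth
rates (0.25 / 0.45 / 0.90), carrying capacities (1500 / 17000 / 45000), the
four critical thresholds, and the per-source variation magnitudes — are
**placeholders**: plausible round numbers chosen once to respect the
slow-fast life-history ordering (moose lowest in growth rate, capacity,
variation and thresholds; ptarmigan highest), documented as such in the
file, and fully overridable. Every structural test in the package is
independent of these values; the factorial summary statistics computed from
them (optimality frequencies, value forgone) are specific to this
parameterization and shift when case-specific values are substituted.

## Evaluation

Ten individual metrics per replicate, all oriented so larger is better:
persistence (0/1); years with the population strictly between the low and
high thresholds ("stable"), strictly above the quasi-extinction and low
thresholds, strictly below the high and overabundance thresholds; mean
yearly harvest; minimum yearly harvest; years with non-zero harvest; and
harvest consistency, defined as 0 minus the standard deviation of yearly
harvests (so 0 is ideal and more variable harvests are more negative).

Standardization maps each metric linearly to 0–100 **within each
environmental context**, using mixed bound regimes:

* persistence and the six year-count metrics have absolute ideals — bounds
  (0, 1) and (0, T) — since "all years stable" is a well-defined best
  outcome regardless of what was simulated;
* `harvest_mean` and `harvest_minimum` are bounded by (0, largest value
  observed over all replications and decision variables in the context), and
  `harvest_consistency` by (−largest observed harvest SD, 0): there is no
  absolute "best possible harvest", so the ensemble defines it.

This makes standardization *relative to the decision-variable sweep*: the
full sweep for a context must be simulated before anything can be scored
(the two-pass architecture of `run_experiment()`), and scores are not
comparable across differently-sized sweeps. Degenerate bounds (best equals
worst, e.g. a sweep in which nothing is ever harvested) score 100 at the
ideal pole and 0 elsewhere, with a warning. Values are clipped to [0, 100]
purely against floating-point overshoot.

Composite scores are unweighted means of member metrics, computed **per
replicate** and then averaged over replicates — not computed from
ensemble-mean metrics — because the metrics co-vary within replicates. The
six sets range from `classic_harv` (persistence, harvest mean) to `complete`
(all ten); persistence is in every set. This linear, equal-weight
aggregation encodes risk-neutral, substitutable preferences; no weighting or
nonlinear utility is offered.

## Decision analysis

From the scored factorial: per (context, set, kind) the best parameters are
the argmax of the mean composite over the kind's grid (ties → earliest grid
point, all ties reported); kinds are then competition-ranked (tied ranks
shared, following ranks skipped). Scores are rounded to 6 decimals before
ranking so that Monte-Carlo-level near-ties count as joint optima; the
rounding is configurable. *Value forgone* of a kind is the optimal kind's
best score minus its own best score — reported both in points on the 0–100
scale and relative to the optimum (%), since either reading of a published
"%" is defensible; the points reading is primary. Value forgone of any
(jointly) optimal kind is exactly 0 by construction.

Pairwise contrasts compare two levels of one factor (species, variability,
start, set, kind) across all matched combinations of the remaining factors,
at the level of best-parameter scores — the only level at which pairs match
exactly across species, whose absolute parameter grids differ. The
information-value analysis partitions the (context, set) cases by an
information level (none, species, variability, start, full environment,
evaluation set, or fully case-specific), chooses one strategy kind per cell
under two rules — most frequently optimal, and minimum mean value forgone,
reported side by side since they can disagree — and reports how often the
choice is optimal and the value it forgoes. With fully case-specific
information both rules achieve 100% optimality and zero forgone value;
under the min-forgone rule the pooled forgone value is non-increasing as the
partition refines (both are tested properties).

## Numerical and reproducibility choices

* Seeds: every replicate's seed is a deterministic hash of (master seed,
  context label, strategy label, replicate index); there is no global RNG
  state shared between cells. Re-running any cell in isolation reproduces
  its rows from a full run.
* Harvest above the available population is capped, not an error: a quota
  can exceed the population (constant rules at low abundance); physically at
  most `N_grow` animals can be removed.
* `sd` of a length-1 harvest series is defined as 0 for the consistency
  metric.
* An optional per-context cache (`cache_dir`) keyed by a configuration hash
  supports resuming large sweeps; any configuration change invalidates it.

## Problem sizes used in the shipped analyses

The default configuration's 1% grids define ~8,600–9,100 decision models per
species per context. The package's own shipped analyses run the same
factorial at reduced resolution, a deliberate scale choice for a
single-machine workflow: the acceptance script uses 5% parameter steps
(401–451 decision models per species) and 100 replicates per scenario; the
test suite's end-to-end factorial uses 10% steps and 60 replicates. Monte
Carlo summaries (composite means) at these scales are stable to well within
the tolerances asserted in the tests; fully converged estimates at 1%/1000
resolution are a matter of compute time, not code path.

## What the synthetic system does and does not show

The simulator *is* the study system here — there is no external data — so
passing tests demonstrate internal correctness (exact deterministic limits,
hand-computable metrics, brute-force-verified optimization, seed-stable
Monte Carlo), not fidelity to any real population. Known structural
limitations, shared with the modelling tradition this follows: a single
closed population with no age, sex or spatial structure; logistic growth
only; no predator-prey coupling (predation is implicit in the variable
growth rate); unbiased noise (no systematic monitoring or implementation
bias); a fixed rule over the timeframe (no within-horizon learning); no
time-discounting, monetary valuation, or stakeholder entitlement framing;
and linear, equal-weight stakeholder utilities. Results conditional on the
placeholder species values — in particular the dominance of
threshold-proportional rules in the optimality frequencies — should be
re-derived with case-specific profiles before being quoted for any real
system.
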
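# Harvest control rules: map an observed population estimate to an initial
# quota. Four kinds: no harvest, constant, proportional, threshold-proportional.

STRATEGY_KINDS <- c("no_harvest", "constant", "proportional", "threshold_proportional")

#' Construct a harvest strategy specification
#'
#' @param kind one of `"no_harvest"`, `"constant"`, `"proportional"`,
#'   `"threshold_proportional"`.
#' @param constant fixed yearly quota in individuals (`constant` only, >= 0).
#' @param proportion fraction of the observed population harvested yearly
#'   (proportional kinds, in \[0, 1\]).
#' @param threshold population threshold in individuals below which (at or
#'   below, comparison is strict) no quota is issued
#'   (`threshold_proportional` only, >= 0).
#' @param fraction,threshold_fraction optional species-relative
#'   parametrization (fraction of the moderate population size) carried along
#'   for cross-species comparisons; purely informational.
#' @param surplus if `TRUE`, the threshold rule harvests
#'   `proportion * (N_obs - threshold)` instead of `proportion * N_obs`
#'   (non-default variant; see Details).
#' @details The default threshold rule takes the set proportion of the whole
#'   population estimate whenever the estimate exceeds the threshold; the
#'   surplus variant harvests only the excess above the threshold.
#' @return an object of class `mse_strategy`.
#' @export
harvest_strategy <- function(kind, constant = NULL, proportion = NULL,
                             threshold = NULL, fraction = NULL,
                             threshold_fraction = NULL, surplus = FALSE) {
  kind <- match.arg(kind, STRATEGY_KINDS)
  spec <- list(kind = kind, surplus = isTRUE(surplus))
  if (kind == "constant") {
    if (is.null(constant) || !is.numeric(constant) || constant < 0)
      mse_abort("mse_invariant_error", "constant strategy requires constant >= 0")
    spec$constant <- as.numeric(constant)
    spec$fraction <- fraction
  } else if (kind %in% c("proportional", "threshold_proportional")) {
    if (is.null(proportion) || !is.numeric(proportion) ||
        proportion < 0 || proportion > 1)
      mse_abort("mse_invariant_error", "%s strategy requires proportion in [0, 1]", kind)
    spec$proportion <- as.numeric(proportion)
    if (kind == "threshold_proportional") {
      if (is.null(threshold) || !is.numeric(threshold) || threshold < 0)
        mse_abort("mse_invariant_error", "threshold_proportional requires threshold >= 0")
      spec$threshold <- as.numeric(threshold)
      spec$threshold_fraction <- threshold_fraction
    }
  }
  structure(spec, class = "mse_strategy")
}

#' Compact text label for a strategy specification
#'
#' Used as the key in result tables and for deterministic per-cell seed
#' derivation, e.g. `"tp(p=0.12,T=450)"`.
#'
#' @param strategy an `mse_strategy`.
#' @return a single string.
#' @export
strategy_label <- function(strategy) {
  switch(strategy$kind,
    no_harvest = "nh",
    constant = sprintf("const(c=%.6g)", strategy$constant),
    proportional = sprintf("prop(p=%.6g)", strategy$proportion),
    threshold_proportional = sprintf("tp(p=%.6g,T=%.6g)",
                                     strategy$proportion, strategy$threshold)
  )
}

#' @export
print.mse_strategy <- function(x, ...) {
  cat(sprintf("<mse_strategy> %s\n", strategy_label(x)))
  invisible(x)
}

#' Convert a population estimate into an initial quota
#'
#' The management decision rule: no harvest yields 0; constant harvest a
#' fixed quota irrespective of the estimate; proportional harvest a set
#' fraction of the estimate; threshold-proportional the same fraction
#' provided the estimate strictly exceeds the threshold (0 otherwise).
#'
#' @param N_obs observed population estimate(s), >= 0 (vectorized).
#' @param strategy an `mse_strategy`.
#' @return quota(s), same length as `N_obs`, all >= 0.
#' @export
set_quota <- function(N_obs, strategy) {
  if (any(N_obs < 0)) mse_abort("mse_domain_error", "N_obs must be >= 0")
  fn <- quota_function(strategy)
  fn(N_obs)
}

# compile the rule once per scenario; the simulator calls the closure yearly
quota_function <- function(strategy) {
  switch(strategy$kind,
    no_harvest = function(N_obs) rep_len(0, length(N_obs)),
    constant = {
      cst <- strategy$constant
      function(N_obs) rep_len(cst, length(N_obs))
    },
    proportional = {
      p <- strategy$proportion
      function(N_obs) p * N_obs
    },
    threshold_proportional = {
      p <- strategy$proportion
      th <- strategy$threshold
      if (isTRUE(strategy$surplus)) {
        function(N_obs) ifelse(N_obs > th, p * (N_obs - th), 0)
      } else {
        function(N_obs) ifelse(N_obs > th, p * N_obs, 0)
      }
    },
    mse_abort("mse_schema_error", "unknown strategy kind: %s", strategy$kind)
  )
}
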
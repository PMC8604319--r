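# Comparative decision analysis: optimal parameters and strategies per
# (environmental context, evaluation set) case, pairwise factor contrasts,
# value forgone, and the information value of knowing the context.

case_key <- function(d) paste(d$species, d$sid, d$set, sep = ":")

#' Competition ranks with shared ranks for ties
#'
#' Descending ranks: the best score gets rank 1; scores within
#' `tie_tolerance` of each other share the smallest applicable rank and the
#' following ranks are skipped (scores 90, 88, 88, 10 rank 1, 2, 2, 4).
#'
#' @param scores numeric vector of per-kind best scores.
#' @param tie_tolerance absolute tolerance within which scores tie
#'   (default 0).
#' @return integer ranks, same length and names as `scores`.
#' @export
rank_strategies <- function(scores, tie_tolerance = 0) {
  ranks <- vapply(scores, function(s)
    1L + sum(scores > s + tie_tolerance), integer(1))
  names(ranks) <- names(scores)
  ranks
}

#' Build the optimality table from an experiment run
#'
#' For every (environmental context, evaluation set, strategy kind): the
#' best mean composite score over the kind's parameter grid and the
#' parameters achieving it (ties broken toward the earliest grid point, all
#' tied optima counted). For every (context, set) case: competition ranks
#' of the four kinds and the set of (jointly) optimal kinds. Scores are
#' rounded to `tie_digits` decimals before ranking so that Monte-Carlo-level
#' near-ties are treated as joint optima; value forgone of any rank-1 kind
#' is exactly 0.
#'
#' @param results an `mse_results` (or its `$scores` data.frame).
#' @param sets evaluation sets to analyse (default: all present).
#' @param tie_digits decimals scores are rounded to for tie detection
#'   (default 6).
#' @return object of class `mse_optimality` with `$by_kind` (one row per
#'   context x set x kind: best score, best parameters, rank, optimality
#'   flag, value forgone in points and relative %) and `$cases` (one row per
#'   context x set: the optimal kind(s)).
#' @export
optimality_table <- function(results, sets = NULL, tie_digits = 6) {
  scores <- if (inherits(results, "mse_results")) results$scores else results
  if (is.null(scores) || nrow(scores) == 0L)
    mse_abort("mse_domain_error", "results table is empty")
  if (is.null(sets)) sets <- unique(scores$set)
  scores <- scores[scores$set %in% sets, , drop = FALSE]
  grp <- interaction(scores$species, scores$sid, scores$set, drop = TRUE)
  rows <- lapply(split(scores, grp), function(d) {
    per_kind <- lapply(split(d, d$kind), function(g) {
      g <- g[order(g$grid_index), , drop = FALSE]
      best <- max(g$score)
      tied <- which(g$score >= best - 10^(-tie_digits) / 2)
      pick <- g[tied[1L], , drop = FALSE]
      data.frame(
        species = pick$species, sid = pick$sid,
        variability = pick$variability, start_scenario = pick$start_scenario,
        set = pick$set, kind = pick$kind,
        best_score = best, best_params = pick$params,
        best_constant = pick$constant, best_proportion = pick$proportion,
        best_threshold = pick$threshold,
        best_constant_frac = pick$constant_frac,
        best_threshold_frac = pick$threshold_frac,
        n_tied_params = length(tied),
        stringsAsFactors = FALSE
      )
    })
    tab <- do.call(rbind, per_kind)
    r <- round(tab$best_score, tie_digits)
    tab$rank <- as.integer(rank_strategies(r))
    tab$optimal <- tab$rank == 1L
    best_overall <- max(tab$best_score)
    tab$value_forgone <- best_overall - tab$best_score
    tab$value_forgone[tab$optimal] <- 0
    tab$value_forgone_rel <- if (best_overall > 0)
      100 * tab$value_forgone / best_overall else 0
    tab
  })
  by_kind <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cases <- do.call(rbind, lapply(rows, function(tab) data.frame(
    species = tab$species[1], sid = tab$sid[1],
    variability = tab$variability[1], start_scenario = tab$start_scenario[1],
    set = tab$set[1],
    optimal_kinds = paste(sort(tab$kind[tab$optimal]), collapse = "+"),
    best_score = max(tab$best_score),
    stringsAsFactors = FALSE
  )))
  rownames(cases) <- NULL
  structure(list(by_kind = by_kind, cases = cases, tie_digits = tie_digits),
            class = "mse_optimality")
}

#' @export
print.mse_optimality <- function(x, ...) {
  freq <- sapply(split(x$by_kind$optimal, x$by_kind$kind), mean)
  cat(sprintf("<mse_optimality> %d context x set cases, %d kinds\n",
              nrow(x$cases), length(freq)))
  cat("  optimality frequency:",
      paste(sprintf("%s %.1f%%", names(freq), 100 * freq), collapse = ", "), "\n")
  invisible(x)
}

#' Best parameters of one strategy kind in one case
#'
#' Argmax of the mean composite score over the kind's parameter grid for a
#' single (context, set) case; ties broken toward the earliest grid point,
#' with all tied optima reported.
#'
#' @param results an `mse_results` (or its `$scores` data.frame).
#' @param species,sid,set,kind case selectors.
#' @param tie_digits tie-detection rounding (default 6 decimals).
#' @return list with `best` (one-row data.frame) and `tied` (all rows within
#'   the tolerance of the maximum, in grid order).
#' @export
select_optimal_parameters <- function(results, species, sid, set, kind,
                                      tie_digits = 6) {
  scores <- if (inherits(results, "mse_results")) results$scores else results
  g <- scores[scores$species == species & scores$sid == sid &
                scores$set == set & scores$kind == kind, , drop = FALSE]
  if (nrow(g) == 0L)
    mse_abort("mse_domain_error",
              "no rows for species=%s sid=%s set=%s kind=%s", species, sid, set, kind)
  g <- g[order(g$grid_index), , drop = FALSE]
  best <- max(g$score)
  tied <- g[g$score >= best - 10^(-tie_digits) / 2, , drop = FALSE]
  list(best = tied[1L, , drop = FALSE], tied = tied)
}

#' Value forgone by always choosing one strategy kind
#'
#' Value forgone is the deficit of the chosen kind's best-parameter score
#' relative to the case's optimal strategy, per (context, set) case; 0
#' whenever the chosen kind is (jointly) optimal. Reported both in points
#' on the 0-100 composite scale and relative to the optimal score (%).
#'
#' @param optimality an `mse_optimality` from [optimality_table()].
#' @param chosen_kind the strategy kind assumed chosen everywhere.
#' @return list with `cases` (per-case value forgone), `mean_points`,
#'   `mean_relative`, and `pct_optimal` (share of cases in which the choice
#'   is optimal, %).
#' @export
compute_value_forgone <- function(optimality, chosen_kind) {
  bk <- optimality$by_kind
  d <- bk[bk$kind == chosen_kind, , drop = FALSE]
  if (nrow(d) == 0L)
    mse_abort("mse_domain_error", "kind '%s' absent from optimality table", chosen_kind)
  list(
    cases = d[, c("species", "sid", "set", "best_score", "rank",
                  "optimal", "value_forgone", "value_forgone_rel")],
    mean_points = mean(d$value_forgone),
    mean_relative = mean(d$value_forgone_rel),
    pct_optimal = 100 * mean(d$optimal)
  )
}

#' Pairwise contrast of one factor across matched cases
#'
#' Pairs every observation at the `left` level of `factor` with the
#' observation at the `right` level whose remaining factors match, and
#' summarizes the paired differences (left minus right). By default the
#' contrast operates on the optimality table's best-parameter composite
#' scores, matching on all of species, variability, starting scenario,
#' evaluation set and strategy kind except the contrasted factor; `value`
#' can instead name an optimal-parameter column (e.g. `"best_proportion"`,
#' `"best_constant_frac"`) for parameter contrasts, in which case constants
#' and thresholds should be taken as the fraction-of-moderate-size columns
#' so that species are comparable.
#'
#' @param x an `mse_optimality`, an `mse_results`, or a data.frame.
#' @param factor one of `"species"`, `"variability"`, `"start_scenario"`,
#'   `"set"`, `"kind"`.
#' @param left,right the two factor levels contrasted.
#' @param value name of the value column (default `"best_score"`).
#' @param by matching columns; default: the standard factors minus `factor`.
#' @return object of class `mse_contrast`: the paired differences and their
#'   summary (median, quartiles, proportions below / equal to / above zero),
#'   plus the count of unmatched observations (excluded).
#' @export
pairwise_contrasts <- function(x, factor, left, right, value = "best_score",
                               by = NULL) {
  d <- if (inherits(x, "mse_optimality")) x$by_kind
       else if (inherits(x, "mse_results")) optimality_table(x)$by_kind
       else x
  if (!factor %in% names(d))
    mse_abort("mse_schema_error", "factor '%s' not a column of the table", factor)
  if (is.null(by))
    by <- setdiff(intersect(c("species", "variability", "start_scenario",
                              "set", "kind"), names(d)), factor)
  dl <- d[d[[factor]] == left, c(by, value), drop = FALSE]
  dr <- d[d[[factor]] == right, c(by, value), drop = FALSE]
  if (nrow(dl) == 0L || nrow(dr) == 0L)
    mse_abort("mse_domain_error", "factor level absent: %s",
              if (nrow(dl) == 0L) left else right)
  m <- merge(dl, dr, by = by, suffixes = c("_left", "_right"))
  n_unmatched <- (nrow(dl) - nrow(m)) + (nrow(dr) - nrow(m))
  if (n_unmatched > 0)
    warning(sprintf("%d unmatched observations excluded from contrast", n_unmatched),
            call. = FALSE)
  diffs <- m[[paste0(value, "_left")]] - m[[paste0(value, "_right")]]
  diffs <- diffs[!is.na(diffs)]
  if (!length(diffs))
    mse_abort("mse_domain_error", "no matched pairs with non-missing values")
  tol <- 1e-9
  structure(list(
    factor = factor, left = left, right = right, value = value,
    differences = diffs,
    n_pairs = length(diffs),
    n_unmatched = n_unmatched,
    median = stats::median(diffs),
    q25 = unname(stats::quantile(diffs, 0.25)),
    q75 = unname(stats::quantile(diffs, 0.75)),
    prop_negative = mean(diffs < -tol),
    prop_zero = mean(abs(diffs) <= tol),
    prop_positive = mean(diffs > tol)
  ), class = "mse_contrast")
}

#' @export
print.mse_contrast <- function(x, ...) {
  cat(sprintf("<mse_contrast> %s: %s vs %s on %s (%d pairs)\n",
              x$factor, x$left, x$right, x$value, x$n_pairs))
  cat(sprintf("  median %.3g [IQR %.3g, %.3g]; <0: %.1f%%, =0: %.1f%%, >0: %.1f%%\n",
              x$median, x$q25, x$q75, 100 * x$prop_negative,
              100 * x$prop_zero, 100 * x$prop_positive))
  invisible(x)
}

heuristic_cell_key <- function(d, level) {
  switch(level,
    none = rep("all", nrow(d)),
    species = d$species,
    variability = d$variability,
    start_population = d$start_scenario,
    full_environment = paste(d$species, d$variability, d$start_scenario, sep = ":"),
    evaluation_set = d$set,
    case = paste(d$species, d$sid, d$set, sep = ":"),
    mse_abort("mse_schema_error", "unknown information level: %s", level)
  )
}

choose_kind <- function(stats_df, rule) {
  # stats_df: one row per kind with freq_optimal and mean_forgone
  ord <- match(stats_df$kind, STRATEGY_KINDS)
  o <- if (rule == "most_frequent")
    order(-stats_df$freq_optimal, stats_df$mean_forgone, ord)
  else
    order(stats_df$mean_forgone, -stats_df$freq_optimal, ord)
  stats_df$kind[o[1L]]
}

#' Information value of context knowledge for strategy choice
#'
#' Partitions the (environmental context, evaluation set) cases by an
#' information level — `"none"` (one pooled cell), `"species"`,
#' `"variability"`, `"start_population"`, `"full_environment"` (species x
#' variability x start), `"evaluation_set"`, or `"case"` (every case its own
#' cell) — and, within each cell, picks a single strategy kind under two
#' selection rules: the kind most frequently optimal among the cell's cases,
#' and the kind with the smallest mean value forgone. Reports, per cell and
#' pooled over all cases, how often the choice is optimal and the mean value
#' forgone it incurs.
#'
#' @param optimality an `mse_optimality` from [optimality_table()].
#' @param level information level (see above).
#' @return object of class `mse_heuristics`: `$cells` (one row per cell x
#'   rule: chosen kind, % optimal, mean value forgone in points and
#'   relative %) and `$pooled` (one row per rule, case-weighted over cells).
#' @export
evaluate_decision_heuristics <- function(optimality, level = "none") {
  bk <- optimality$by_kind
  bk$cell <- heuristic_cell_key(bk, level)
  cells <- list(); pooled <- list()
  for (rule in c("most_frequent", "min_forgone")) {
    per_cell <- lapply(split(bk, bk$cell), function(d) {
      st <- do.call(rbind, lapply(split(d, d$kind), function(g) data.frame(
        kind = g$kind[1], freq_optimal = mean(g$optimal),
        mean_forgone = mean(g$value_forgone),
        mean_forgone_rel = mean(g$value_forgone_rel),
        stringsAsFactors = FALSE
      )))
      chosen <- choose_kind(st, rule)
      cs <- st[st$kind == chosen, ]
      data.frame(
        rule = rule, cell = d$cell[1],
        n_cases = sum(d$kind == chosen),
        chosen_kind = chosen,
        pct_optimal = 100 * cs$freq_optimal,
        mean_value_forgone = cs$mean_forgone,
        mean_value_forgone_rel = cs$mean_forgone_rel,
        stringsAsFactors = FALSE
      )
    })
    ct <- do.call(rbind, c(per_cell, list(make.row.names = FALSE)))
    w <- ct$n_cases / sum(ct$n_cases)
    pooled[[rule]] <- data.frame(
      rule = rule,
      pct_optimal = sum(w * ct$pct_optimal),
      mean_value_forgone = sum(w * ct$mean_value_forgone),
      mean_value_forgone_rel = sum(w * ct$mean_value_forgone_rel),
      stringsAsFactors = FALSE
    )
    cells[[rule]] <- ct
  }
  structure(list(
    level = level,
    cells = do.call(rbind, c(cells, list(make.row.names = FALSE))),
    pooled = do.call(rbind, c(pooled, list(make.row.names = FALSE)))
  ), class = "mse_heuristics")
}

#' @export
print.mse_heuristics <- function(x, ...) {
  cat(sprintf("<mse_heuristics> information level: %s\n", x$level))
  for (i in seq_len(nrow(x$pooled)))
    cat(sprintf("  rule %-14s: optimal in %.1f%% of cases, mean value forgone %.2f points (%.2f%% of optimum)\n",
                x$pooled$rule[i], x$pooled$pct_optimal[i],
                x$pooled$mean_value_forgone[i], x$pooled$mean_value_forgone_rel[i]))
  invisible(x)
}
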
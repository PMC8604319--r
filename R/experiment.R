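# Experiment orchestration: the full factorial sweep over environmental
# contexts x strategies x parameter grids, with the two-pass evaluation
# (simulate everything, resolve context-relative bounds, then score).

#' Run the full factorial MSE experiment
#'
#' For every environmental context, simulates every decision-grid cell
#' (strategy x parameters) for the context's species, resolves the
#' standardization bounds from the pooled ensemble of all cells, and
#' computes standardized metrics and composite scores. Randomness is fully
#' determined by the master seed: every replicate's seed is derived from
#' (master seed, context, strategy label, replicate), so any cell re-run in
#' isolation reproduces its rows exactly and results are independent of
#' execution order.
#'
#' @param config an `mse_config`.
#' @param n_replicates,master_seed optional overrides of the corresponding
#'   experiment settings.
#' @param keep_replicates if `TRUE`, retain the per-replicate composite
#'   scores (`$replicates`, long data.frame); memory scales with
#'   cells x replicates x sets.
#' @param cache_dir optional directory for per-context raw-metric caches
#'   keyed by the configuration hash; a changed configuration invalidates
#'   the cache.
#' @param verbose print one progress line per completed context.
#' @return object of class `mse_results`: `$scores` (one row per context x
#'   strategy x parameters x set, with the mean composite score and
#'   distribution summaries), optional `$replicates`, and `$provenance`
#'   (master seed, replicate count, configuration hash).
#' @export
run_experiment <- function(config, n_replicates = NULL, master_seed = NULL,
                           keep_replicates = FALSE, cache_dir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(config, "mse_config"))
  if (!is.null(n_replicates))
    config$experiment$n_replicates <- as.integer(n_replicates)
  if (!is.null(master_seed))
    config$experiment$master_seed <- as.integer(master_seed)
  ex <- config$experiment
  sets <- ex$evaluation_sets
  hash <- config_hash(config)
  contexts <- build_environmental_grid(config)
  score_rows <- list()
  rep_rows <- list()
  for (ctx in contexts) {
    grid <- build_decision_grid(config, ctx$species)
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, sprintf("raw_%s_%s.rds", hash, ctx$label))
    if (!is.null(cache_dir) && file.exists(cache_file)) {
      raw_cells <- readRDS(cache_file)
    } else {
      raw_cells <- lapply(grid, function(strat) {
        sc <- simulate_scenario(ctx, strat, config)
        scenario_raw_metrics(sc, config)
      })
      if (!is.null(cache_dir)) {
        dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
        saveRDS(raw_cells, cache_file)
      }
    }
    bounds <- resolve_bounds(do.call(rbind, raw_cells), ex$timeframe)
    for (k in seq_along(grid)) {
      strat <- grid[[k]]
      std <- standardize_metrics(raw_cells[[k]], bounds)
      comp <- composite_scores(std, sets)
      row <- data.frame(
        species = ctx$species$name,
        sid = ctx$sid,
        variability = ctx$variability,
        start_scenario = ctx$start_scenario,
        context = ctx$label,
        kind = strat$kind,
        params = strategy_label(strat),
        constant = strat$constant %||% NA_real_,
        proportion = strat$proportion %||% NA_real_,
        threshold = strat$threshold %||% NA_real_,
        constant_frac = strat$fraction %||% NA_real_,
        threshold_frac = strat$threshold_fraction %||% NA_real_,
        grid_index = k,
        stringsAsFactors = FALSE
      )
      score_rows[[length(score_rows) + 1L]] <-
        cbind(row[rep(1L, nrow(comp$summary)), , drop = FALSE], comp$summary,
              row.names = NULL)
      if (keep_replicates) {
        n <- nrow(comp$replicate)
        rep_rows[[length(rep_rows) + 1L]] <- data.frame(
          context = ctx$label, kind = strat$kind, params = row$params,
          replicate = rep(seq_len(n), times = length(sets)),
          set = rep(sets, each = n),
          score = as.vector(comp$replicate),
          stringsAsFactors = FALSE
        )
      }
    }
    if (verbose)
      message(sprintf("context %-24s done: %d cells x %d replicates",
                      ctx$label, length(grid), ex$n_replicates))
  }
  structure(list(
    scores = do.call(rbind, score_rows),
    replicates = if (keep_replicates) do.call(rbind, rep_rows),
    provenance = list(master_seed = ex$master_seed,
                      n_replicates = ex$n_replicates,
                      timeframe = ex$timeframe,
                      config_hash = hash,
                      sets = sets,
                      n_contexts = length(contexts))
  ), class = "mse_results")
}

#' @export
print.mse_results <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<mse_results> %d contexts | %d score rows | %d replicates | seed %d | config %s\n",
              p$n_contexts, nrow(x$scores), p$n_replicates, p$master_seed,
              p$config_hash))
  invisible(x)
}

#' @export
summary.mse_results <- function(object, threshold = 85, ...) {
  summarize_run(object, threshold = threshold)
}

#' Summarize a completed experiment run
#'
#' Reports, over the optimized (context x strategy x set) cases — each
#' strategy kind at its best parameters — the per-context score ranges, the
#' share of cases whose mean composite exceeds a threshold, and the count of
#' maximal (score 100) cases.
#'
#' @param results an `mse_results` (or its `$scores` data.frame).
#' @param threshold composite-score threshold for the exceedance count
#'   (default 85).
#' @return object of class `mse_run_summary` with fields `n_cases`,
#'   `n_above_threshold`, `pct_above_threshold`, `n_maximal`, and a
#'   per-context range table.
#' @export
summarize_run <- function(results, threshold = 85) {
  scores <- if (inherits(results, "mse_results")) results$scores else results
  if (is.null(scores) || nrow(scores) == 0L)
    mse_abort("mse_domain_error", "results table is empty")
  opt <- optimality_table(results)
  cases <- opt$by_kind
  ranges <- do.call(rbind, lapply(split(scores, scores$context), function(d)
    data.frame(context = d$context[1], min_score = min(d$score),
               max_score = max(d$score), row.names = NULL)))
  structure(list(
    n_cases = nrow(cases),
    threshold = threshold,
    n_above_threshold = sum(cases$best_score > threshold),
    pct_above_threshold = 100 * mean(cases$best_score > threshold),
    n_maximal = sum(cases$best_score >= 100 - 1e-9),
    context_ranges = ranges[order(ranges$context), ]
  ), class = "mse_run_summary")
}

#' @export
print.mse_run_summary <- function(x, ...) {
  cat(sprintf("<mse_run_summary> %d optimized context x strategy x set cases\n", x$n_cases))
  cat(sprintf("  above %g: %d (%.1f%%); maximal (=100): %d\n",
              x$threshold, x$n_above_threshold, x$pct_above_threshold, x$n_maximal))
  cat(sprintf("  contexts: %d; score range %.1f-%.1f\n",
              nrow(x$context_ranges), min(x$context_ranges$min_score),
              max(x$context_ranges$max_score)))
  invisible(x)
}

#' Write an experiment run to a directory
#'
#' Writes `scores.csv`, optionally `replicates.csv`, and a JSON
#' `manifest.json` holding provenance (configuration hash, master seed,
#' package version, timestamps) and the table row counts.
#'
#' @param results an `mse_results`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_run <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(results$scores, file.path(dir, "scores.csv"), row.names = FALSE)
  tables <- list(scores = nrow(results$scores))
  if (!is.null(results$replicates)) {
    utils::write.csv(results$replicates, file.path(dir, "replicates.csv"),
                     row.names = FALSE)
    tables$replicates <- nrow(results$replicates)
  }
  manifest <- c(results$provenance, list(
    package_version = as.character(utils::packageVersion("harvestMSE")),
    written_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    tables = tables
  ))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Read an experiment run written by [write_run()]
#'
#' @param dir run directory containing `scores.csv` and `manifest.json`.
#' @return an `mse_results`.
#' @export
read_run <- function(dir) {
  sf <- file.path(dir, "scores.csv")
  if (!file.exists(sf))
    mse_abort("mse_missing_file_error", "no scores.csv under %s", dir)
  scores <- utils::read.csv(sf, stringsAsFactors = FALSE)
  mf <- file.path(dir, "manifest.json")
  prov <- if (file.exists(mf)) jsonlite::read_json(mf, simplifyVector = TRUE) else list()
  rf <- file.path(dir, "replicates.csv")
  structure(list(
    scores = scores,
    replicates = if (file.exists(rf)) utils::read.csv(rf, stringsAsFactors = FALSE),
    provenance = prov
  ), class = "mse_results")
}
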
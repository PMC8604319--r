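# helper: build a synthetic scores table (one context, one set) with known
# per-cell scores, for exercising the optimizer against brute force
synthetic_scores <- function(scores_by_cell, set = "complete",
                             species = "testium", sid = 1L) {
  rows <- lapply(seq_along(scores_by_cell), function(k) {
    cell <- scores_by_cell[[k]]
    data.frame(
      species = species, sid = sid, variability = "low",
      start_scenario = "moderate", context = paste0(species, "_sid", sid),
      kind = cell$kind, params = cell$params,
      constant = cell$constant %||% NA_real_,
      proportion = cell$proportion %||% NA_real_,
      threshold = cell$threshold %||% NA_real_,
      constant_frac = NA_real_, threshold_frac = NA_real_,
      grid_index = k, set = set, score = cell$score,
      score_sd = 0, q25 = cell$score, q50 = cell$score, q75 = cell$score,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_cells <- function() list(
  list(kind = "no_harvest", params = "nh", score = 40),
  list(kind = "constant", params = "const(c=10)", constant = 10, score = 55),
  list(kind = "constant", params = "const(c=20)", constant = 20, score = 71),
  list(kind = "constant", params = "const(c=30)", constant = 30, score = 62),
  list(kind = "proportional", params = "prop(p=0.1)", proportion = 0.1, score = 80),
  list(kind = "proportional", params = "prop(p=0.2)", proportion = 0.2, score = 90),
  list(kind = "proportional", params = "prop(p=0.3)", proportion = 0.3, score = 85),
  list(kind = "threshold_proportional", params = "tp(p=0.1,T=100)",
       proportion = 0.1, threshold = 100, score = 88),
  list(kind = "threshold_proportional", params = "tp(p=0.2,T=100)",
       proportion = 0.2, threshold = 100, score = 86),
  list(kind = "threshold_proportional", params = "tp(p=0.3,T=100)",
       proportion = 0.3, threshold = 100, score = 84)
)

test_that("optimal-parameter selection matches exhaustive enumeration on a toy grid", {
  tab <- synthetic_scores(toy_cells())
  # independent oracle: brute-force maximum per kind
  for (kind in unique(tab$kind)) {
    d <- tab[tab$kind == kind, ]
    oracle_best <- d[which.max(d$score), ]
    sel <- select_optimal_parameters(tab, "testium", 1L, "complete", kind)
    expect_equal(sel$best$score, max(d$score))
    expect_equal(sel$best$params, oracle_best$params)
    expect_equal(nrow(sel$tied), 1L)
  }
  # unimodal proportional curve peaks at p = 0.2
  expect_equal(select_optimal_parameters(tab, "testium", 1L, "complete",
                                         "proportional")$best$proportion, 0.2)
  # no-harvest has a single score
  expect_equal(select_optimal_parameters(tab, "testium", 1L, "complete",
                                         "no_harvest")$best$score, 40)
  expect_error(select_optimal_parameters(tab, "testium", 1L, "complete", "nope"),
               class = "mse_domain_error")
})

test_that("constant score curves report the first grid point with all optima tied", {
  cells <- lapply(1:3, function(k)
    list(kind = "constant", params = sprintf("const(c=%d)", 10 * k),
         constant = 10 * k, score = 50))
  tab <- synthetic_scores(cells)
  sel <- select_optimal_parameters(tab, "testium", 1L, "complete", "constant")
  expect_equal(sel$best$constant, 10)
  expect_equal(nrow(sel$tied), 3L)
})

test_that("strategy ranking uses competition ranks with shared ties", {
  expect_equal(unname(rank_strategies(c(90, 88, 88, 10))), c(1L, 2L, 2L, 4L))
  expect_equal(unname(rank_strategies(c(88, 90, 10, 88))), c(2L, 1L, 4L, 2L))
  expect_equal(unname(rank_strategies(c(50, 50))), c(1L, 1L))
  expect_equal(unname(rank_strategies(c(90, 88.4, 88, 10), tie_tolerance = 0.5)),
               c(1L, 2L, 2L, 4L))
})

test_that("the optimality table ranks kinds and computes value forgone against the optimum", {
  tab <- synthetic_scores(toy_cells())
  opt <- optimality_table(tab)
  bk <- opt$by_kind
  expect_equal(nrow(bk), 4L)
  # oracle by enumeration: best per kind 40, 71, 90, 88
  expect_equal(bk$best_score[match(c("no_harvest", "constant", "proportional",
                                     "threshold_proportional"), bk$kind)],
               c(40, 71, 90, 88))
  expect_equal(bk$rank[match(c("proportional", "threshold_proportional",
                               "constant", "no_harvest"), bk$kind)],
               1:4)
  expect_equal(opt$cases$optimal_kinds, "proportional")
  vf <- bk$value_forgone[match(c("proportional", "threshold_proportional",
                                 "constant", "no_harvest"), bk$kind)]
  expect_equal(vf, c(0, 2, 19, 50))
  expect_equal(bk$value_forgone_rel[bk$kind == "threshold_proportional"],
               100 * 2 / 90)
  # the optimal choice forgoes exactly zero
  expect_equal(compute_value_forgone(opt, "proportional")$mean_points, 0)
  expect_equal(compute_value_forgone(opt, "no_harvest")$mean_points, 50)
  expect_equal(compute_value_forgone(opt, "no_harvest")$pct_optimal, 0)
})

test_that("optimality is invariant to the row order of the results table", {
  tab <- synthetic_scores(toy_cells())
  set.seed(5)
  shuffled <- tab[sample(nrow(tab)), ]
  o1 <- optimality_table(tab)
  o2 <- optimality_table(shuffled)
  expect_equal(o1$by_kind[order(o1$by_kind$kind), ],
               o2$by_kind[order(o2$by_kind$kind), ],
               ignore_attr = TRUE)
})

test_that("near-ties within the rounding tolerance are reported as joint optima", {
  cells <- list(
    list(kind = "proportional", params = "prop(p=0.1)", proportion = 0.1,
         score = 90),
    list(kind = "threshold_proportional", params = "tp(p=0.1,T=100)",
         proportion = 0.1, threshold = 100, score = 90 - 1e-9),
    list(kind = "no_harvest", params = "nh", score = 10)
  )
  opt <- optimality_table(synthetic_scores(cells))
  expect_equal(opt$cases$optimal_kinds, "proportional+threshold_proportional")
  expect_equal(sum(opt$by_kind$optimal), 2L)
  # value forgone of every jointly optimal kind is exactly zero
  expect_equal(opt$by_kind$value_forgone[opt$by_kind$optimal], c(0, 0))
})

test_that("pairwise contrasts summarize matched differences with exhaustive pairing", {
  tab1 <- synthetic_scores(toy_cells(), sid = 1L)
  tab2 <- synthetic_scores(toy_cells(), sid = 2L)
  tab2$variability <- "high"
  both <- rbind(tab1, tab2)
  opt <- optimality_table(both)
  # identical per-kind best scores at both levels -> all differences zero
  ct <- pairwise_contrasts(opt, "variability", "low", "high")
  expect_equal(ct$n_pairs, 4L)  # 4 kinds x 1 species x 1 start x 1 set
  expect_equal(ct$differences, rep(0, 4))
  expect_equal(c(ct$prop_negative, ct$prop_zero, ct$prop_positive), c(0, 1, 0))

  # left level exceeding right by 2 everywhere
  shifted <- both
  shifted$score[shifted$variability == "low"] <-
    shifted$score[shifted$variability == "low"] + 2
  ct2 <- pairwise_contrasts(optimality_table(shifted), "variability", "low", "high")
  expect_equal(ct2$median, 2)
  expect_equal(ct2$prop_positive, 1)
  expect_equal(ct2$prop_negative + ct2$prop_zero + ct2$prop_positive, 1)
})

test_that("decision heuristics quantify the value of context information", {
  # two contexts x one set, different optimal kinds, known value forgone
  cells_a <- toy_cells()  # optimal: proportional (90), tp best 88
  cells_b <- list(
    list(kind = "no_harvest", params = "nh", score = 20),
    list(kind = "constant", params = "const(c=10)", constant = 10, score = 50),
    list(kind = "proportional", params = "prop(p=0.1)", proportion = 0.1, score = 70),
    list(kind = "threshold_proportional", params = "tp(p=0.1,T=100)",
         proportion = 0.1, threshold = 100, score = 95)
  )
  tab <- rbind(synthetic_scores(cells_a, sid = 1L),
               {
                 t2 <- synthetic_scores(cells_b, sid = 3L)
                 t2$start_scenario <- "quasi_extinction"
                 t2
               })
  opt <- optimality_table(tab)
  h_none <- evaluate_decision_heuristics(opt, "none")
  # pooled, no information: proportional optimal in 1/2 cases, forgone (0+25)/2;
  # threshold-proportional forgone (2+0)/2 = 1 -> min-forgone picks tp
  pooled <- h_none$pooled
  mf <- pooled[pooled$rule == "min_forgone", ]
  expect_equal(mf$mean_value_forgone, 1)
  cells_df <- h_none$cells
  expect_equal(cells_df$chosen_kind[cells_df$rule == "min_forgone"],
               "threshold_proportional")
  # proportional and tp are each optimal in 1 of 2 cases; the frequency tie
  # is broken toward the lower mean forgone (tp: 1 < proportional: 12.5)
  expect_equal(cells_df$chosen_kind[cells_df$rule == "most_frequent"],
               "threshold_proportional")
  expect_equal(mf$pct_optimal, 50)
  expect_error(evaluate_decision_heuristics(opt, "galactic"),
               class = "mse_schema_error")

  # information fine enough to isolate every case: always optimal, zero forgone
  h_case <- evaluate_decision_heuristics(opt, "case")
  expect_equal(h_case$pooled$pct_optimal, c(100, 100))
  expect_equal(h_case$pooled$mean_value_forgone, c(0, 0))

  # refining information never increases the min-forgone mean value forgone
  vf <- sapply(c("none", "start_population", "case"), function(lv) {
    p <- evaluate_decision_heuristics(opt, lv)$pooled
    p$mean_value_forgone[p$rule == "min_forgone"]
  })
  expect_true(all(diff(vf) <= 1e-12))
})
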
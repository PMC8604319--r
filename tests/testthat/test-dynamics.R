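test_that("logistic step matches the closed form and its fixed points", {
  expect_equal(logistic_step(0, 0.5, 1200), 0)
  expect_equal(logistic_step(1200, 0.5, 1200), 1200)
  expect_equal(logistic_step(600, 0.1, 1200), 630)
  # floor at zero for pathological negative growth
  expect_equal(logistic_step(100, -2, 1200), 0)
  expect_error(logistic_step(100, 0.1, 0), class = "mse_domain_error")
})

test_that("variation draws collapse to their centers when all sds are zero", {
  sp <- test_species(sd_all = 0)
  d <- draw_variation(sp, "high", timeframe = 15, seed = 1)
  expect_equal(d$r, rep(sp$r_mean, 15))
  expect_equal(d$m, rep(1, 15))
  expect_equal(d$q, rep(1, 15))
  expect_equal(d$h, rep(1, 15))
})

test_that("variation draws respect their truncation bounds", {
  sp <- test_species(sd_all = 1.5)  # extreme sigma to stress the bounds
  mins <- Inf
  for (i in 1:300) {
    d <- draw_variation(sp, "high", timeframe = 20, seed = i)
    mins <- min(mins, d$m, d$q, d$h)
    expect_true(all(d$r >= sp$r_bounds[1] & d$r <= sp$r_bounds[2]))
  }
  expect_gte(mins, 0)
})

test_that("truncated-normal sampler matches the analytic truncated mean", {
  # independent oracle: closed-form mean of a normal truncated at [lo, hi]
  tn_mean <- function(mu, sd, lo, hi) {
    a <- (lo - mu) / sd; b <- (hi - mu) / sd
    mu + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
  }
  set.seed(123)
  for (par in list(c(mu = 1, sd = 0.2, lo = 0, hi = Inf),
                   c(mu = 1, sd = 0.2, lo = 0.9, hi = 1.05),
                   c(mu = 0, sd = 1, lo = 1, hi = Inf))) {
    x <- rtrunc_norm(1e5, par["mu"], par["sd"], par["lo"], par["hi"])
    expect_true(all(x >= par["lo"] & x <= par["hi"]))
    se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - tn_mean(par["mu"], par["sd"], par["lo"], par["hi"])),
              3 * se)
  }
  expect_equal(rtrunc_norm(3, mean = 2, sd = 0, lower = 0, upper = 1), rep(1, 3))
})

test_that("zero-variability no-harvest trajectory equals the deterministic logistic iteration", {
  cfg <- test_config(sd_all = 0)
  sp <- cfg$species$testium
  ctx <- environmental_context(sp, "low", "moderate")
  ctx$N0 <- 300  # start below the moderate size to see growth
  tr <- simulate_replicate(ctx, harvest_strategy("no_harvest"), cfg, 1L)
  expected <- numeric(20); N <- 300
  for (t in 1:20) {
    N <- N + sp$r_mean * N * (1 - N / sp$K)
    expected[t] <- N
  }
  expect_identical(tr$N, expected)
  expect_false(tr$extinct)
  expect_equal(tr$H, rep(0, 20))
  # monotone approach to K from below under no harvest
  expect_true(all(diff(c(300, tr$N)) > 0))
  expect_true(all(tr$N < sp$K))
})

test_that("a constant quota at or above K wipes out a small population in year one", {
  cfg <- test_config(sd_all = 0)
  sp <- cfg$species$testium
  ctx <- environmental_context(sp, "low", "quasi_extinction")  # N0 = 100
  tr <- simulate_replicate(ctx, harvest_strategy("constant", constant = sp$K),
                           cfg, 1L)
  N1_grow <- logistic_step(100, sp$r_mean, sp$K)
  expect_equal(tr$H[1], N1_grow)   # harvest capped at the available population
  expect_equal(tr$N[1], 0)
  expect_true(tr$extinct)
  expect_equal(tr$extinction_year, 1L)
  expect_equal(tr$H[-1], rep(0, 19))  # absorbing state
  expect_equal(tr$N[-1], rep(0, 19))
})

test_that("threshold zero and proportional strategies give bitwise-identical trajectories", {
  cfg <- test_config(sd_all = 0.2, n_replicates = 5)
  ctx <- environmental_context(cfg$species$testium, "high", "moderate")
  pr <- harvest_strategy("proportional", proportion = 0.15)
  tp <- harvest_strategy("threshold_proportional", proportion = 0.15, threshold = 0)
  s1 <- simulate_replicate(ctx, pr, cfg, 99L)
  s2 <- simulate_replicate(ctx, tp, cfg, 99L)
  expect_identical(s1$N, s2$N)
  expect_identical(s1$H, s2$H)
  # degenerate strategies are pairwise identical to no harvest under shared seeds
  nh <- simulate_replicate(ctx, harvest_strategy("no_harvest"), cfg, 99L)
  c0 <- simulate_replicate(ctx, harvest_strategy("constant", constant = 0), cfg, 99L)
  p0 <- simulate_replicate(ctx, harvest_strategy("proportional", proportion = 0), cfg, 99L)
  expect_identical(nh$N, c0$N)
  expect_identical(nh$N, p0$N)
  expect_identical(nh$H, p0$H)
})

test_that("scenario simulation is seed-stable and consistent with single replicates", {
  cfg <- test_config(sd_all = 0.15, n_replicates = 8)
  ctx <- environmental_context(cfg$species$testium, "high", "overabundance")
  st <- harvest_strategy("proportional", proportion = 0.2)
  a <- simulate_scenario(ctx, st, cfg)
  b <- simulate_scenario(ctx, st, cfg)
  expect_identical(a$N, b$N)
  expect_identical(a$H, b$H)
  # replicate i of the scenario equals simulate_replicate at the derived seed
  for (i in c(1L, 5L)) {
    seed_i <- hash_seed(cfg$experiment$master_seed, ctx$label,
                        strategy_label(st), i)
    tr <- simulate_replicate(ctx, st, cfg, seed_i)
    expect_identical(tr$N, a$N[i, ])
    expect_identical(tr$H, a$H[i, ])
  }
  # zero-variability scenario: all replicates identical
  cfg0 <- test_config(sd_all = 0, n_replicates = 4)
  s0 <- simulate_scenario(environmental_context(cfg0$species$testium, "low", "moderate"),
                          st, cfg0)
  expect_true(all(apply(s0$N, 2, function(col) length(unique(col)) == 1L)))
})

test_that("trajectories conserve individuals and never over-harvest", {
  cfg <- test_config(sd_all = 0.4, n_replicates = 30, master_seed = 3)
  ctx <- environmental_context(cfg$species$testium, "high", "quasi_extinction")
  for (st in list(harvest_strategy("constant", constant = 80),
                  harvest_strategy("proportional", proportion = 0.4),
                  harvest_strategy("threshold_proportional", proportion = 0.4,
                                   threshold = 300))) {
    sc <- simulate_scenario(ctx, st, cfg)
    expect_true(all(sc$H >= 0))
    expect_true(all(sc$H <= sc$N_pre + 1e-12))
    expect_true(all(sc$N >= 0))
    # conservation: N = N_pre - H exactly, except where floored to extinction
    resid <- sc$N_pre - sc$H - sc$N
    floored <- sc$N == 0 & (sc$N_pre - sc$H) < cfg$experiment$extinction_floor
    expect_true(all(abs(resid[!floored]) < 1e-9))
    expect_true(all(resid[floored] >= 0))
    # absorbing extinction: after the extinction year everything is zero
    for (i in which(sc$extinct)) {
      y <- sc$extinction_year[i]
      if (y < ncol(sc$N)) {
        expect_equal(sc$N[i, (y + 1):ncol(sc$N)], rep(0, ncol(sc$N) - y))
        expect_equal(sc$H[i, (y + 1):ncol(sc$N)], rep(0, ncol(sc$N) - y))
      }
    }
  }
})
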
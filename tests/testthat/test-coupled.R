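make_cpue_panel <- function(values) cpue_panel(values, "detrended")

test_that("season mapping splits rows and commutes with bay permutation", {
  set.seed(30)
  v <- matrix(exp(rnorm(70 * 7, 0, 0.2)), 70, 7)
  panel <- make_cpue_panel(v)
  m <- map_seasons(panel)
  expect_identical(dim(m$high), c(35L, 7L))
  expect_identical(dim(m$low), c(35L, 7L))
  expect_equal(unname(m$high[1, ]), v[1, ])  # spring yr 1 -> high season yr 1
  expect_equal(unname(m$low[1, ]), v[2, ])
  perm <- sample(7)
  mp <- map_seasons(make_cpue_panel(v[, perm]))
  expect_equal(unname(mp$high), unname(m$high[, perm]))
})

test_that("recreational scaling anchors the long-run mean at the base rate", {
  base_rates <- c(0.1, 0.3, 0.2)
  const <- matrix(rep(c(2, 5, 1), each = 10), 10, 3)
  out <- scale_to_recreational(const, base_rates)
  expect_equal(unname(out), matrix(rep(base_rates, each = 10), 10, 3),
               tolerance = 1e-12)
  set.seed(31)
  sim <- matrix(exp(rnorm(30, 0, 0.4)), 10, 3)
  out1 <- scale_to_recreational(sim, base_rates)
  expect_equal(unname(colMeans(out1)), base_rates, tolerance = 1e-12)
  expect_equal(scale_to_recreational(2 * sim, base_rates), out1,
               tolerance = 1e-12)
  # hand-set 3-step series
  s <- matrix(c(1, 2, 3), 3, 1)
  expect_equal(unname(scale_to_recreational(s, 0.4)),
               matrix(0.4 * c(1, 2, 3) / 2, 3, 1), tolerance = 1e-12)
  expect_error(scale_to_recreational(matrix(0, 3, 1), 0.4), "positive")
})

test_that("at base catch the trajectory reproduces the base trip table", {
  base <- texas_base_tables()
  coefs <- choice_coefs()
  # simulated CPUE constant at its long-run mean => base trips exactly
  flat <- make_cpue_panel(matrix(1, 70, 7))
  traj <- simulate_trips(flat, flat, base, coefs, demand_scenario(1, coefs))
  for (season in c("high", "low")) {
    d <- traj[traj$season == season, ]
    per_bay <- tapply(d$trips, d$bay, unique)
    expect_equal(as.numeric(per_bay[base[[season]]$bay]),
                 base[[season]]$trips, tolerance = 1e-6)
  }
  # probabilities normalize within every season-step
  sums <- tapply(traj$Pj, interaction(traj$season, traj$year), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("lambda -> 0 freezes participation so only site shares move", {
  base <- texas_base_tables()
  coefs <- choice_coefs()
  set.seed(33)
  red <- make_cpue_panel(matrix(exp(rnorm(70 * 7, 0, 0.3)), 70, 7))
  trout <- make_cpue_panel(matrix(exp(rnorm(70 * 7, 0, 0.3)), 70, 7))
  sc0 <- demand_scenario(1, coefs)
  sc0$lambda <- 0
  traj <- simulate_trips(red, trout, base, coefs, sc0)
  pt_base <- base_participation(sum(base$high$trips), sum(base$low$trips))
  expect_true(all(abs(traj$PT[traj$season == "high"] - pt_base$high) < 1e-12))
  expect_true(all(abs(traj$PT[traj$season == "low"] - pt_base$low) < 1e-12))
  expect_gt(sd(traj$Pj[traj$season == "high" & traj$bay == "GL"]), 0)
})

test_that("one coupling step matches a hand-computed two-bay example", {
  # two bays, one year: logit shares and the linearized participation
  # response computed by hand
  base2 <- list(
    high = structure(data.frame(bay = c("A", "B"), trips = c(600, 400),
                                harvest_red_drum = c(120, 40),
                                harvest_seatrout = c(300, 400)),
                     season = "high",
                     class = c("base_season_table", "data.frame")),
    low = structure(data.frame(bay = c("A", "B"), trips = c(300, 200),
                               harvest_red_drum = c(30, 30),
                               harvest_seatrout = c(60, 90)),
                    season = "low",
                    class = c("base_season_table", "data.frame")))
  coefs <- choice_coefs(-0.05, 0.2, 0.3)
  sc <- demand_scenario(1, coefs, wtp = 30, annual_days = 20,
                        days_high = 189, days_low = 176)
  # catch doubles in bay A in year 1 (both species), constant elsewhere
  red <- matrix(1, 4, 2); trout <- matrix(1, 4, 2)
  red[1, 1] <- 2; trout[1, 1] <- 2
  # the scaling anchor is the mean over the 2 simulated years
  panel_r <- cpue_panel(red, "detrended", bays = c("A", "B"))
  panel_t <- cpue_panel(trout, "detrended", bays = c("A", "B"))
  traj <- simulate_trips(panel_r, panel_t, base2, coefs, sc)

  rates <- base_catch_rates(base2$high)
  d <- unclass(calibrate_distances(base2$high, coefs))
  mean_a <- mean(c(2, 1))
  cr <- c(rates$red_drum[1] * 2 / mean_a, rates$red_drum[2])
  ct <- c(rates$spotted_seatrout[1] * 2 / mean_a, rates$spotted_seatrout[2])
  u <- coefs$beta_d * d + coefs$beta_cR * cr + coefs$beta_cS * ct
  pj_hand <- as.numeric(exp(u) / sum(exp(u)))
  iv_hand <- log(sum(exp(u)))
  u0 <- coefs$beta_d * d + coefs$beta_cR * rates$red_drum +
    coefs$beta_cS * rates$spotted_seatrout
  iv0_hand <- log(sum(exp(u0)))
  pt0 <- base_participation(1000, 500, 20, 189, 176)$high
  pt_hand <- pt0 + sc$lambda * (1 - pt0) * pt0 * (iv_hand - iv0_hand)
  n_season <- 1000 / pt0
  got <- traj[traj$season == "high" & traj$year == 1, ]
  expect_equal(got$Pj, pj_hand, tolerance = 1e-12)
  expect_equal(got$PT, rep(pt_hand, 2), tolerance = 1e-12)
  expect_equal(got$trips, as.numeric(n_season * pt_hand * pj_hand),
               tolerance = 1e-10)
})

test_that("scenario runs share the catch draw and differ only through lambda", {
  base <- texas_base_tables()
  coefs <- choice_coefs()
  set.seed(34)
  red <- make_cpue_panel(matrix(exp(rnorm(70 * 7, 0, 0.3)), 70, 7))
  trout <- make_cpue_panel(matrix(exp(rnorm(70 * 7, 0, 0.3)), 70, 7))
  out <- run_scenarios(red, trout, base, coefs)
  expect_named(out, c("cpm_0.5", "cpm_1", "cpm_2"))
  expect_equal(out$cpm_0.5$Pj, out$cpm_2$Pj, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(out$cpm_0.5$PT, out$cpm_2$PT)))
  lam <- sapply(out, function(t) attr(t, "scenario")$lambda)
  expect_equal(unname(lam), lambda_from_wtp(coefs$beta_d, 30, c(0.5, 1, 2)),
               tolerance = 1e-12)
  expect_identical(run_scenarios(red, trout, base, coefs,
                                 cost_per_mile = numeric(0)),
                   setNames(list(), character(0)))
  # summaries expose per-bay trip dispersion
  s <- summary(out$cpm_1)
  expect_true(all(c("mean_trips", "sd_trips", "cv_trips") %in% names(s)))
  expect_identical(nrow(s), 14L)
})
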
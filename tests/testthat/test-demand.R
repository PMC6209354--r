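coefs_t1 <- choice_coefs()  # published site-choice estimates

test_that("base catch rates are landings per trip and invert exactly", {
  b <- table2_high()
  r <- base_catch_rates(b)
  expect_equal(r$red_drum[1], 30997 / 191165, tolerance = 1e-12)
  expect_equal(r$red_drum * b$trips, b$harvest_red_drum, tolerance = 1e-12)
  expect_equal(r$spotted_seatrout * b$trips, b$harvest_seatrout,
               tolerance = 1e-12)
  zero <- base_season_table("high", rep(10, 7), rep(0, 7), rep(0, 7))
  expect_true(all(base_catch_rates(zero)$red_drum == 0))
})

test_that("site-choice probabilities are a proper softmax", {
  # identical bays split evenly
  p <- site_choice_probs(rep(0.2, 7), rep(0.9, 7), rep(100, 7), coefs_t1)
  expect_equal(p, rep(1 / 7, 7), tolerance = 1e-12)
  # translation invariance in distance
  set.seed(4)
  cr <- runif(7); ct <- runif(7); d <- runif(7, 80, 120)
  expect_equal(site_choice_probs(cr, ct, d, coefs_t1),
               site_choice_probs(cr, ct, d + 57.3, coefs_t1),
               tolerance = 1e-12)
  expect_equal(sum(site_choice_probs(cr, ct, d, coefs_t1)), 1,
               tolerance = 1e-12)
  # overflow safety
  expect_false(anyNA(site_choice_probs(cr * 1e4, ct * 1e4, d, coefs_t1)))
})

test_that("calibrated distances reproduce the observed trip shares", {
  for (season in c("high", "low")) {
    b <- texas_base_tables()[[season]]
    d <- calibrate_distances(b, coefs_t1)
    r <- base_catch_rates(b)
    p <- site_choice_probs(r$red_drum, r$spotted_seatrout, unclass(d),
                           coefs_t1)
    expect_equal(p, b$trips / sum(b$trips), tolerance = 1e-10)
  }
  # share identity for Galveston specifically
  b <- table2_high()
  r <- base_catch_rates(b)
  d <- calibrate_distances(b, coefs_t1)
  p1 <- site_choice_probs(r$red_drum, r$spotted_seatrout, unclass(d),
                          coefs_t1)[1]
  expect_equal(p1, 191165 / 631950, tolerance = 1e-10)
})

test_that("calibration round trip holds for random positive base tables", {
  for (seed in 1:30) {
    set.seed(seed)
    b <- base_season_table("high", trips = runif(7, 1e3, 2e5),
                           harvest_red_drum = runif(7, 0, 5e4),
                           harvest_seatrout = runif(7, 0, 1e5))
    d <- calibrate_distances(b, coefs_t1)
    r <- base_catch_rates(b)
    p <- site_choice_probs(r$red_drum, r$spotted_seatrout, unclass(d),
                           coefs_t1)
    expect_equal(p, b$trips / sum(b$trips), tolerance = 1e-10)
  }
  # equal trips and equal rates -> all distances at the anchor
  be <- base_season_table("high", rep(1e4, 7), rep(2e3, 7), rep(4e3, 7))
  expect_equal(as.numeric(calibrate_distances(be, coefs_t1)),
               rep(100, 7), tolerance = 1e-10)
  expect_error(
    calibrate_distances(be, structure(list(beta_d = 0, beta_cR = 1,
                                           beta_cS = 1),
                                      class = "choice_coefs")),
    "no solution")
})

test_that("inclusive value is an overflow-safe log-sum-exp", {
  one <- inclusive_value(0.5, 0.2, 50, coefs_t1)
  u <- coefs_t1$beta_d * 50 + coefs_t1$beta_cR * 0.5 + coefs_t1$beta_cS * 0.2
  expect_equal(one, u, tolerance = 1e-12)
  J <- 6
  expect_equal(inclusive_value(rep(0.5, J), rep(0.2, J), rep(50, J), coefs_t1),
               u + log(J), tolerance = 1e-12)
  b <- table2_high()
  r <- base_catch_rates(b)
  d <- unclass(calibrate_distances(b, coefs_t1))
  uvec <- coefs_t1$beta_d * d + coefs_t1$beta_cR * r$red_drum +
    coefs_t1$beta_cS * r$spotted_seatrout
  expect_equal(inclusive_value(r$red_drum, r$spotted_seatrout, d, coefs_t1),
               log(sum(exp(uvec))), tolerance = 1e-12)
})

test_that("lambda calibration is linear in WTP and inverse in cost", {
  expect_equal(lambda_from_wtp(-0.082, 30, 1.0), 2.46, tolerance = 1e-12)
  expect_equal(lambda_from_wtp(-0.082, 30, 2.0), 1.23, tolerance = 1e-12)
  expect_identical(lambda_from_wtp(-0.082, 0, 5), 0)
  expect_equal(lambda_from_wtp(-0.082, 60, 1), 2 * 2.46, tolerance = 1e-12)
  expect_equal(lambda_from_wtp(-0.082, 30, 0.5), 2 * 2.46, tolerance = 1e-12)
  expect_error(lambda_from_wtp(-0.082, 30, 0), "positive")
})

test_that("seasonal participation conserves the annual rate exactly", {
  pt <- base_participation(sum(table2_high()$trips), sum(table2_low()$trips))
  expect_lt(abs(pt$high - 0.0749), 1e-4)   # printed precision
  expect_lt(abs(pt$low - 0.0332), 1e-4)
  expect_equal((pt$high * 189 + pt$low * 176) / 365, 20 / 365,
               tolerance = 1e-12)
  sym <- base_participation(5e5, 5e5, 20, 182.5, 182.5)
  expect_equal(sym$high, 20 / 365, tolerance = 1e-12)
  expect_equal(sym$low, 20 / 365, tolerance = 1e-12)
  for (seed in 1:10) {
    set.seed(seed)
    th <- runif(1, 1e4, 1e6); tl <- runif(1, 1e4, 1e6)
    dh <- runif(1, 100, 250); dl <- 365 - dh
    pt <- base_participation(th, tl, 20, dh, dl)
    expect_equal((pt$high * dh + pt$low * dl) / 365, 20 / 365,
                 tolerance = 1e-12)
  }
})

test_that("participation response matches hand arithmetic and the logistic", {
  expect_identical(delta_trip_probability(1.3, 1.3, 0.07, 2.46), 0)
  hand <- 2.46 * (1 - 0.0749) * 0.0749 * 0.01
  expect_equal(delta_trip_probability(1.01, 1.00, 0.0749, 2.46), hand,
               tolerance = 1e-12)
  # exact-logistic mode agrees to first order as the IV change shrinks
  gaps <- sapply(c(1e-2, 1e-4, 1e-6), function(h) {
    lin <- delta_trip_probability(1 + h, 1, 0.0749, 2.46)
    ex <- delta_trip_probability(1 + h, 1, 0.0749, 2.46, exact = TRUE)
    abs(ex - lin) / abs(lin)
  })
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[3], 1e-5)
})

test_that("trip elasticity components match the finite-difference oracle", {
  b <- table2_high()
  r <- base_catch_rates(b)
  d <- unclass(calibrate_distances(b, coefs_t1))
  pt0 <- base_participation(sum(table2_high()$trips),
                            sum(table2_low()$trips))$high
  lambda <- lambda_from_wtp(coefs_t1$beta_d, 30, 1)
  iv0 <- inclusive_value(r$red_drum, r$spotted_seatrout, d, coefs_t1)
  alpha <- qlogis(pt0) - lambda * iv0
  for (j in c(1L, 4L, 7L)) {
    for (sp in c("red_drum", "spotted_seatrout")) {
      pj <- site_choice_probs(r$red_drum, r$spotted_seatrout, d, coefs_t1)[j]
      cj <- r[[sp]][j]
      el <- trip_elasticity(coefs_t1, lambda, pt0, pj, cj, sp)
      expect_equal(el$total, el$participation + el$site_choice,
                   tolerance = 1e-12)
      # central finite difference of ln(PT * Pj) in ln cj through the full
      # logit + exact logistic participation with alpha held fixed
      fd <- local({
        h <- 1e-6
        eval_at <- function(mult) {
          cr <- r$red_drum; ct <- r$spotted_seatrout
          if (sp == "red_drum") cr[j] <- cr[j] * mult else ct[j] <- ct[j] * mult
          pjv <- site_choice_probs(cr, ct, d, coefs_t1)[j]
          iv <- inclusive_value(cr, ct, d, coefs_t1)
          ptv <- plogis(alpha + lambda * iv)
          log(ptv * pjv)
        }
        (eval_at(exp(h)) - eval_at(exp(-h))) / (2 * h)
      })
      expect_equal(el$total, fd, tolerance = 1e-5)
    }
  }
  # degenerate cases vanish
  expect_identical(trip_elasticity(coefs_t1, 2.46, 0.07, 0.2, 0,
                                   "red_drum")$total, 0)
  zero_beta <- structure(list(beta_d = -0.08, beta_cR = 0, beta_cS = 0),
                         class = "choice_coefs")
  expect_identical(trip_elasticity(zero_beta, 2.46, 0.07, 0.2, 0.5,
                                   "red_drum")$total, 0)
})

test_that("expectation smoothing reduces to its closed-form corners", {
  base_rates <- c(0.2, 0.4)
  dist <- matrix(c(0, 10, 10, 0), 2, 2)
  w <- list(decay_rate = 0.08, omega_wv = 0.35, omega_yr = 0.84)
  # anomalies of zero leave the base rates untouched
  obs0 <- data.frame(site = c(1L, 2L), wave_lag = 0L, year_lag = 0L,
                     value = base_rates)
  expect_equal(expected_catch(obs0, w, dist, base_rates), base_rates,
               tolerance = 1e-12)
  # single own-site current observation dominates when others have weight 0
  w1 <- list(decay_rate = 1, omega_wv = 0, omega_yr = 0)
  obs1 <- data.frame(site = 1L, wave_lag = 0L, year_lag = 0L, value = 0.9)
  out <- suppressWarnings(expected_catch(obs1, w1, dist, base_rates))
  expect_equal(out[1], 0.9, tolerance = 1e-12)
  expect_equal(out[2], base_rates[2], tolerance = 1e-12)  # zero-weight fallback
  # two sites, two periods against a hand computation
  obs2 <- data.frame(site = c(1L, 2L, 1L), wave_lag = c(0L, 0L, 1L),
                     year_lag = c(0L, 0L, 0L), value = c(0.5, 0.1, 0.3))
  wts1 <- c((1 - 0.08)^0, (1 - 0.08)^10, (1 - 0.08)^0 * 0.35)
  hand1 <- sum(wts1 * (obs2$value - base_rates[obs2$site])) / sum(wts1) +
    base_rates[1]
  expect_equal(expected_catch(obs2, w, dist, base_rates)[1], hand1,
               tolerance = 1e-12)
})

test_that("the elasticity table spans scenarios, seasons and species", {
  tab <- elasticity_table(texas_base_tables(), coefs_t1)
  expect_identical(nrow(tab), 3L * 2L * 2L * 7L)
  expect_true(all(tab$elasticity > 0))
  expect_equal(tab$elasticity, tab$participation + tab$site_choice,
               tolerance = 1e-12)
  # stronger catch response for seatrout (larger beta_c and catch rates)
  m <- tapply(tab$elasticity, tab$species, mean)
  expect_gt(m[["spotted_seatrout"]], m[["red_drum"]])
})
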
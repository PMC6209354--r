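#' Map monitoring seasons to fishing seasons
#'
#' Spring monitoring CPUE informs anglers during the following summer (high
#' season) and fall CPUE during the following winter (low season) of the same
#' model year: odd panel rows feed the high season, even rows the low season.
#'
#' @param panel a [cpue_panel()] with rows alternating spring/fall.
#' @return list with `high` and `low` year-by-bay matrices.
#' @export
map_seasons <- function(panel) {
  v <- unclass(panel)
  if (nrow(v) %% 2L != 0L)
    stop("panel must have an even number of rows (whole years)")
  list(high = v[seq(1L, nrow(v), by = 2L), , drop = FALSE],
       low = v[seq(2L, nrow(v), by = 2L), , drop = FALSE])
}

#' Scale monitoring CPUE to recreational catch per trip
#'
#' Recreational catch rates are assumed proportional to the gillnet
#' monitoring CPUE; each bay's simulated series is anchored so its long-run
#' mean equals the base recreational catch rate:
#' c_rec = c_base * sim / mean_t(sim).
#'
#' @param sim_cpue year-by-bay matrix of simulated positive CPUE for one
#'   season.
#' @param base_rates per-bay base catch per trip (the anchor).
#' @return year-by-bay matrix of expected recreational catch per trip.
#' @export
scale_to_recreational <- function(sim_cpue, base_rates) {
  sim_cpue <- as.matrix(sim_cpue)
  stopifnot(ncol(sim_cpue) == length(base_rates))
  mu <- colMeans(sim_cpue)
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("each bay needs a positive long-run mean simulated CPUE")
  sweep(sweep(sim_cpue, 2, mu, "/"), 2, base_rates, "*")
}

#' Demand scenario constants
#'
#' Bundles the behavioural constants of one travel-cost scenario: the cost
#' per one-way mile, the willingness to pay used to calibrate the
#' dissimilarity coefficient, and the season structure used for base
#' participation.
#'
#' @param cost_per_mile $ per one-way mile.
#' @param coefs a [choice_coefs()] (supplies beta_d for lambda).
#' @param wtp willingness to pay per fishing day ($, default 30).
#' @param annual_days fishing days per angler-year (default 20).
#' @param days_high,days_low season lengths in days.
#' @return A `demand_scenario` list with `lambda` filled in.
#' @export
demand_scenario <- function(cost_per_mile, coefs = choice_coefs(), wtp = 30,
                            annual_days = 20, days_high = 189,
                            days_low = 176) {
  structure(list(cost_per_mile = cost_per_mile,
                 lambda = lambda_from_wtp(coefs$beta_d, wtp, cost_per_mile),
                 wtp = wtp, annual_days = annual_days,
                 days_high = days_high, days_low = days_low),
            class = "demand_scenario")
}

#' Simulate seasonal trips per bay from simulated catch
#'
#' The coupling step: simulated CPUE panels for the two species are mapped to
#' fishing seasons, rescaled to recreational catch rates, and pushed through
#' the demand model year by year. Site-choice probabilities come from the
#' conditional logit at the calibrated distances; participation moves with
#' the inclusive value via the linearized logistic response (clamped to
#' \[0, 1\]); trips to bay j are N_season * P_T * P_j, with the total trip
#' occasions N_season backed out from the base trips and base participation.
#' When the simulated catch sits at its long-run mean, the trajectory
#' reproduces the base trip table exactly.
#'
#' @param sim_red,sim_trout positive CPUE panels (year-by-bay after season
#'   mapping happens internally; rows alternate spring/fall).
#' @param base list with `high`/`low` [base_season_table()]s.
#' @param coefs a [choice_coefs()].
#' @param scenario a [demand_scenario()].
#' @param distances optional list with `high`/`low` [calibrate_distances()]
#'   vectors; calibrated from `base` when omitted.
#' @param exact_pt use the exact logistic participation response instead of
#'   the linearization.
#' @return A `trip_trajectory` data frame: `cost_per_mile`, `year`, `season`,
#'   `bay`, `trips`, `PT`, `Pj`, with the scenario attached as an attribute.
#' @export
simulate_trips <- function(sim_red, sim_trout, base, coefs, scenario,
                           distances = NULL, exact_pt = FALSE) {
  if (is.null(distances))
    distances <- list(high = calibrate_distances(base$high, coefs),
                      low = calibrate_distances(base$low, coefs))
  red <- map_seasons(sim_red)
  trout <- map_seasons(sim_trout)
  pt_base <- base_participation(sum(base$high$trips), sum(base$low$trips),
                                scenario$annual_days, scenario$days_high,
                                scenario$days_low)
  rows <- list()
  n_clamped <- 0L
  for (season in c("high", "low")) {
    b <- base[[season]]
    rates <- base_catch_rates(b)
    d <- unclass(distances[[season]])
    c_red <- scale_to_recreational(red[[season]], rates$red_drum)
    c_trout <- scale_to_recreational(trout[[season]], rates$spotted_seatrout)
    iv_base <- inclusive_value(rates$red_drum, rates$spotted_seatrout, d,
                               coefs)
    n_season <- sum(b$trips) / pt_base[[season]]
    for (y in seq_len(nrow(c_red))) {
      pj <- site_choice_probs(c_red[y, ], c_trout[y, ], d, coefs)
      iv <- inclusive_value(c_red[y, ], c_trout[y, ], d, coefs)
      pt <- pt_base[[season]] +
        delta_trip_probability(iv, iv_base, pt_base[[season]],
                               scenario$lambda, exact = exact_pt)
      if (pt < 0 || pt > 1) n_clamped <- n_clamped + 1L
      pt <- min(max(pt, 0), 1)
      rows[[length(rows) + 1L]] <- data.frame(
        cost_per_mile = scenario$cost_per_mile, year = y, season = season,
        bay = b$bay, trips = n_season * pt * pj, PT = pt, Pj = pj,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (n_clamped > 0L)
    message("participation linearization left [0, 1] in ", n_clamped,
            " season-steps (clamped)")
  structure(out, scenario = scenario, n_clamped = n_clamped,
            class = c("trip_trajectory", "data.frame"))
}

#' @export
print.trip_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf(
    "Trip trajectory: %d years x 2 seasons x %d bays (cpm $%.2f, lambda %.3f)\n",
    length(unique(x$year)), length(unique(x$bay)), sc$cost_per_mile,
    sc$lambda))
  print(utils::head(as.data.frame(x), 7L))
  cat("...\n")
  invisible(x)
}

#' @export
summary.trip_trajectory <- function(object, ...) {
  agg <- do.call(rbind, lapply(split(object, list(object$season, object$bay)),
    function(d) data.frame(season = d$season[1], bay = d$bay[1],
                           mean_trips = mean(d$trips), sd_trips = stats::sd(d$trips),
                           cv_trips = stats::sd(d$trips) / mean(d$trips))))
  rownames(agg) <- NULL
  agg[order(agg$season, match(agg$bay, bay_codes())), ]
}

#' @export
plot.trip_trajectory <- function(x, season = "high", ...) {
  d <- x[x$season == season, ]
  bays <- unique(d$bay)
  m <- sapply(bays, function(b) d$trips[d$bay == b])
  graphics::matplot(unique(d$year), m / 1000, type = "l", lty = 1,
                    xlab = "Year", ylab = "Trips (thousands)",
                    main = sprintf("Simulated %s-season trips (cpm $%.2f)",
                                   season, attr(x, "scenario")$cost_per_mile),
                    ...)
  graphics::legend("topright", legend = bays, col = seq_along(bays), lty = 1,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' Run the coupled simulation under several travel-cost scenarios
#'
#' One trip trajectory per cost-per-mile value, each with its own calibrated
#' lambda, driven by the same simulated catch panels so trajectories differ
#' only through the scenario.
#'
#' @param sim_red,sim_trout simulated positive CPUE panels.
#' @param base list with `high`/`low` [base_season_table()]s.
#' @param coefs a [choice_coefs()].
#' @param cost_per_mile vector of one-way costs per mile (default 0.5, 1, 2).
#' @param ... passed to [demand_scenario()] and [simulate_trips()].
#' @return named list of `trip_trajectory` objects (possibly empty).
#' @export
run_scenarios <- function(sim_red, sim_trout, base, coefs = choice_coefs(),
                          cost_per_mile = c(0.5, 1, 2), ...) {
  dots <- list(...)
  sc_args <- dots[names(dots) %in%
                    c("wtp", "annual_days", "days_high", "days_low")]
  st_args <- dots[names(dots) %in% c("distances", "exact_pt")]
  out <- lapply(cost_per_mile, function(cpm) {
    sc <- do.call(demand_scenario, c(list(cost_per_mile = cpm, coefs = coefs),
                                     sc_args))
    do.call(simulate_trips, c(list(sim_red = sim_red, sim_trout = sim_trout,
                                   base = base, coefs = coefs, scenario = sc),
                              st_args))
  })
  stats::setNames(out, sprintf("cpm_%g", cost_per_mile))
}
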
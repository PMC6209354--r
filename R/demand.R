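#' Base expected catch per trip from effort and landings
#'
#' The representative angler's expected catch of each species at each bay is
#' the seasonal landings divided by the seasonal trips.
#'
#' @param base a [base_season_table()].
#' @return data frame with columns `bay`, `red_drum`, `spotted_seatrout`
#'   (fish per trip).
#' @export
base_catch_rates <- function(base) {
  if (any(base$trips <= 0)) stop("trip counts must be positive")
  data.frame(bay = base$bay,
             red_drum = base$harvest_red_drum / base$trips,
             spotted_seatrout = base$harvest_seatrout / base$trips,
             stringsAsFactors = FALSE)
}

# linear site utilities: beta_d d + beta_cR cR + beta_cS cS
site_utilities <- function(catch_red, catch_trout, distances, coefs) {
  stopifnot(length(catch_red) == length(distances),
            length(catch_trout) == length(distances))
  as.numeric(coefs$beta_d * unclass(distances) +
               coefs$beta_cR * catch_red + coefs$beta_cS * catch_trout)
}

#' Conditional-logit site-choice probabilities
#'
#' The probability of a trip going to bay j is the softmax of the linear
#' utilities in distance and expected catch of the two species (computed with
#' a max shift for overflow safety). Probabilities sum to one and are
#' invariant to adding a constant to every distance.
#'
#' @param catch_red,catch_trout per-bay expected catch per trip.
#' @param distances per-bay one-way distances (miles).
#' @param coefs a [choice_coefs()].
#' @return numeric vector of per-bay probabilities.
#' @export
site_choice_probs <- function(catch_red, catch_trout, distances, coefs) {
  u <- site_utilities(catch_red, catch_trout, distances, coefs)
  eu <- exp(u - max(u))
  eu / sum(eu)
}

#' Inclusive value of a trip
#'
#' The log-sum-exp of the site utilities: the expected utility of taking a
#' trip, which links site choice to the participation decision.
#'
#' @inheritParams site_choice_probs
#' @return scalar inclusive value.
#' @export
inclusive_value <- function(catch_red, catch_trout, distances, coefs) {
  u <- site_utilities(catch_red, catch_trout, distances, coefs)
  m <- max(u)
  m + log(sum(exp(u - m)))
}

#' Calibrate the representative angler's distance vector
#'
#' Solves the share-matching system: given the observed trip shares and base
#' catch rates, finds the distances a hypothetical representative angler
#' would have to face for the logit model to reproduce the observed
#' distribution of trips across bays, after anchoring the first bay's
#' distance at `d1`. In closed form,
#' d_j = d1 + \[ln(T_j/T_1) + ln C_1 - ln C_j\] / beta_d with
#' ln C_j = beta_cR cR_j + beta_cS cS_j.
#'
#' @param base a [base_season_table()].
#' @param coefs a [choice_coefs()].
#' @param d1 anchor distance for the first bay (miles, default 100).
#' @return A `distance_vector`: named per-bay distances with `season` and
#'   `d1` attributes.
#' @export
calibrate_distances <- function(base, coefs, d1 = 100) {
  if (coefs$beta_d == 0) stop("beta_d = 0: the system has no solution")
  rates <- base_catch_rates(base)
  lnC <- coefs$beta_cR * rates$red_drum + coefs$beta_cS * rates$spotted_seatrout
  d <- d1 + (log(base$trips / base$trips[1]) + lnC[1] - lnC) / coefs$beta_d
  structure(stats::setNames(d, base$bay), season = attr(base, "season"),
            d1 = d1, class = "distance_vector")
}

#' @export
print.distance_vector <- function(x, ...) {
  cat(sprintf("Calibrated distance vector (%s season, anchor %.0f mi):\n",
              attr(x, "season"), attr(x, "d1")))
  print(round(stats::setNames(as.numeric(x), names(x)), 1))
  invisible(x)
}

#' Expectation-smoothed catch rates
#'
#' An angler's expected catch at a site is a weighted average of observed
#' catch-rate anomalies at nearby sites in the current and previous year,
#' added back to the site's historical average: weights decay geometrically
#' with distance ((1 - rate)^miles), with the wave lag within the year
#' (omega_wv per wave), and with the year lag (omega_yr per year).
#'
#' @param obs data frame of dated observations: columns `site` (index into
#'   `base_rates`), `wave_lag` (0 = current wave), `year_lag` (0 = current
#'   year), `value` (observed catch rate).
#' @param weights list with `decay_rate` (per-mile decline, in \[0,1\]),
#'   `omega_wv`, `omega_yr` (both in \[0,1\]).
#' @param site_distances square matrix of inter-site miles.
#' @param base_rates per-site historical average catch.
#' @return per-site expected catch vector. When every weight is zero for a
#'   site the historical average is returned for it (with a warning).
#' @export
expected_catch <- function(obs, weights, site_distances, base_rates) {
  n <- length(base_rates)
  stopifnot(nrow(site_distances) == n, ncol(site_distances) == n)
  if (any(weights$decay_rate < 0 | weights$decay_rate > 1) ||
      weights$omega_wv < 0 || weights$omega_wv > 1 ||
      weights$omega_yr < 0 || weights$omega_yr > 1)
    stop("weights must lie in [0, 1]")
  out <- numeric(n)
  degenerate <- FALSE
  for (j in seq_len(n)) {
    w <- (1 - weights$decay_rate)^site_distances[obs$site, j] *
      weights$omega_wv^obs$wave_lag * weights$omega_yr^obs$year_lag
    if (sum(w) <= 0) {
      out[j] <- base_rates[j]
      degenerate <- TRUE
    } else {
      anom <- sum(w * (obs$value - base_rates[obs$site])) / sum(w)
      out[j] <- anom + base_rates[j]
    }
  }
  if (degenerate)
    warning("all smoothing weights zero for some site(s); ",
            "falling back to the historical average")
  out
}

#' Dissimilarity coefficient from willingness to pay
#'
#' Calibrates the nested-logit dissimilarity coefficient from the estimated
#' distance coefficient and the willingness to pay for a fishing day:
#' lambda = -(beta_d / cost_per_mile) * WTP. The distance coefficient equals
#' a travel-cost coefficient only at $1 per one-way mile; other costs rescale
#' it.
#'
#' @param beta_d distance coefficient (negative).
#' @param wtp willingness to pay per fishing day ($, default 30).
#' @param cost_per_mile one-way travel cost per mile ($, positive).
#' @return lambda (positive for negative `beta_d`).
#' @export
lambda_from_wtp <- function(beta_d, wtp = 30, cost_per_mile = 1) {
  if (any(cost_per_mile <= 0)) stop("cost_per_mile must be positive")
  if (any(wtp < 0)) stop("wtp must be non-negative")
  -(beta_d / cost_per_mile) * wtp
}

#' Seasonal base participation probabilities
#'
#' Spreads the annual probability of fishing on a given day
#' (`annual_days`/365) across the high and low seasons proportionally to
#' their base trip totals, so the weighted annual average is conserved
#' exactly: PT_high = (annual_days/365) (365/days_high)
#' T_high/(T_high + T_low), and PT_low scaled so the identity
#' (PT_low days_low + PT_high days_high)/365 = annual_days/365 holds.
#'
#' @param trips_high,trips_low total seasonal trips.
#' @param annual_days fishing days per angler-year (default 20).
#' @param days_high,days_low season lengths in days (defaults 189 and 176).
#' @return list with `high` and `low` daily trip probabilities.
#' @export
base_participation <- function(trips_high, trips_low, annual_days = 20,
                               days_high = 189, days_low = 176) {
  if (trips_high <= 0) stop("trips_high must be positive")
  if (trips_low < 0 || annual_days <= 0 || days_high <= 0 || days_low <= 0)
    stop("inputs must be positive")
  pt_high <- (annual_days / 365) * (365 / days_high) *
    (trips_high / (trips_high + trips_low))
  pt_low <- (trips_low / trips_high) * pt_high * (days_high / days_low)
  list(high = pt_high, low = pt_low)
}

#' Change in trip probability from a change in inclusive value
#'
#' Default is the linear approximation dPT = lambda (1 - PT) PT (IV -
#' IV_base) around the base participation probability. The exact-logistic
#' mode recovers the implied intercept alpha = logit(PT_base) - lambda
#' IV_base and returns the exact difference of logistic probabilities.
#'
#' @param iv,iv_base inclusive values (scenario and base).
#' @param pt_base base participation probability in (0, 1).
#' @param lambda dissimilarity coefficient.
#' @param exact use the exact logistic instead of the linearization.
#' @return the change in participation probability.
#' @export
delta_trip_probability <- function(iv, iv_base, pt_base, lambda,
                                   exact = FALSE) {
  if (pt_base <= 0 || pt_base >= 1) stop("pt_base must lie in (0, 1)")
  if (!exact)
    return(lambda * (1 - pt_base) * pt_base * (iv - iv_base))
  alpha <- stats::qlogis(pt_base) - lambda * iv_base
  stats::plogis(alpha + lambda * iv) - pt_base
}

#' Elasticity of trips to a bay with respect to its catch rate
#'
#' The percentage change in the unconditional probability of a trip to bay j
#' (participation times site choice) per percentage change in its expected
#' catch, split into the participation component
#' lambda (1 - PT) beta_c P_j c_j and the site-choice component
#' beta_c c_j (1 - P_j).
#'
#' @param coefs a [choice_coefs()].
#' @param lambda dissimilarity coefficient.
#' @param pt participation probability in (0, 1).
#' @param pj site-choice probability of bay j in (0, 1).
#' @param cj expected catch of the species at bay j (fish per trip).
#' @param species `"red_drum"` or `"spotted_seatrout"` (selects beta_c).
#' @return list: `participation`, `site_choice`, `total`.
#' @export
trip_elasticity <- function(coefs, lambda, pt, pj, cj,
                            species = c("red_drum", "spotted_seatrout")) {
  species <- match.arg(species)
  if (pt <= 0 || pt >= 1 || pj <= 0 || pj >= 1)
    stop("pt and pj must lie strictly in (0, 1)")
  if (cj < 0) stop("cj must be non-negative")
  beta_c <- if (species == "red_drum") coefs$beta_cR else coefs$beta_cS
  e_part <- lambda * (1 - pt) * beta_c * pj * cj
  e_site <- beta_c * cj * (1 - pj)
  list(participation = e_part, site_choice = e_site,
       total = e_part + e_site)
}

#' Elasticity table across bays, seasons and cost scenarios
#'
#' Evaluates [trip_elasticity()] at the base catch rates and base trip
#' shares for every bay, species and season, for each travel-cost scenario's
#' lambda.
#'
#' @param base list with `high`/`low` [base_season_table()]s.
#' @param coefs a [choice_coefs()].
#' @param cost_per_mile vector of one-way costs per mile.
#' @param wtp willingness to pay per trip.
#' @param annual_days,days_high,days_low passed to [base_participation()].
#' @return data frame: `cost_per_mile`, `lambda`, `season`, `species`, `bay`,
#'   `elasticity` and its two components.
#' @export
elasticity_table <- function(base, coefs, cost_per_mile = c(0.5, 1, 2),
                             wtp = 30, annual_days = 20, days_high = 189,
                             days_low = 176) {
  pt <- base_participation(sum(base$high$trips), sum(base$low$trips),
                           annual_days, days_high, days_low)
  out <- list()
  for (cpm in cost_per_mile) {
    lambda <- lambda_from_wtp(coefs$beta_d, wtp, cpm)
    for (season in c("high", "low")) {
      b <- base[[season]]
      rates <- base_catch_rates(b)
      pj <- b$trips / sum(b$trips)
      for (sp in c("red_drum", "spotted_seatrout")) {
        cj <- rates[[sp]]
        el <- lapply(seq_along(pj), function(j)
          trip_elasticity(coefs, lambda, pt[[season]], pj[j], cj[j], sp))
        out[[length(out) + 1L]] <- data.frame(
          cost_per_mile = cpm, lambda = lambda, season = season,
          species = sp, bay = b$bay,
          participation = vapply(el, `[[`, numeric(1), "participation"),
          site_choice = vapply(el, `[[`, numeric(1), "site_choice"),
          elasticity = vapply(el, `[[`, numeric(1), "total"),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
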
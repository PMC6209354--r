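#' Texas bay codes in coastal order
#'
#' The seven major Texas bays, ordered along the coast from northeast to
#' southwest. All spatial neighbour indexing in the process-error band of the
#' state-space model derives from this order.
#'
#' @return Character vector of 7 bay codes: Galveston (GL), Matagorda (MG),
#'   San Antonio (SA), Aransas (AR), Corpus Christi (CC), Upper Laguna Madre
#'   (UL), Lower Laguna Madre (LL).
#' @export
bay_codes <- function() c("GL", "MG", "SA", "AR", "CC", "UL", "LL")

#' @rdname bay_codes
#' @export
bay_names <- function() {
  c(GL = "Galveston", MG = "Matagorda", SA = "San Antonio", AR = "Aransas",
    CC = "Corpus Christi", UL = "Upper Laguna Madre", LL = "Lower Laguna Madre")
}

species_codes <- function() c("red_drum", "spotted_seatrout")

#' Site-choice utility coefficients
#'
#' Bundles the conditional-logit utility coefficients: disutility of distance
#' (per one-way mile) and the marginal utility of expected catch of each
#' species (per fish per trip). Defaults are the published estimates for Gulf
#' of Mexico day-trip anglers.
#'
#' @param beta_d utility per mile of one-way distance; must be negative.
#' @param beta_cR utility per expected red drum caught per trip.
#' @param beta_cS utility per expected spotted seatrout caught per trip.
#' @return An object of class `choice_coefs`.
#' @export
choice_coefs <- function(beta_d = -0.082, beta_cR = 0.170, beta_cS = 0.347) {
  stopifnot(is.numeric(beta_d), length(beta_d) == 1L, is.finite(beta_d))
  if (beta_d >= 0) stop("'beta_d' must be negative (distance is a cost)")
  structure(list(beta_d = beta_d, beta_cR = beta_cR, beta_cS = beta_cS),
            class = "choice_coefs")
}

#' @export
print.choice_coefs <- function(x, ...) {
  cat("Site-choice coefficients:\n")
  cat(sprintf("  beta_d  (per mile):          %8.4f\n", x$beta_d))
  cat(sprintf("  beta_cR (per red drum):      %8.4f\n", x$beta_cR))
  cat(sprintf("  beta_cS (per seatrout):      %8.4f\n", x$beta_cS))
  invisible(x)
}

#' Base-season effort and harvest table
#'
#' Per-bay private-boat trips and landed fish of each species for one fishing
#' season, used to calibrate the representative angler. Bays must follow the
#' coastal order of [bay_codes()].
#'
#' @param season `"high"` (summer) or `"low"` (winter).
#' @param trips numeric vector of 7 trip counts, all positive.
#' @param harvest_red_drum,harvest_seatrout numeric vectors of 7 landings
#'   counts, non-negative.
#' @return A `base_season_table` data frame with columns `bay`, `trips`,
#'   `harvest_red_drum`, `harvest_seatrout` and a `season` attribute.
#' @export
base_season_table <- function(season, trips, harvest_red_drum,
                              harvest_seatrout) {
  season <- match.arg(season, c("high", "low"))
  stopifnot(length(trips) == 7L, length(harvest_red_drum) == 7L,
            length(harvest_seatrout) == 7L)
  if (any(!is.finite(trips)) || any(trips <= 0))
    stop("all trip counts must be positive")
  if (any(harvest_red_drum < 0) || any(harvest_seatrout < 0))
    stop("harvests must be non-negative")
  out <- data.frame(bay = bay_codes(), trips = as.numeric(trips),
                    harvest_red_drum = as.numeric(harvest_red_drum),
                    harvest_seatrout = as.numeric(harvest_seatrout),
                    stringsAsFactors = FALSE)
  attr(out, "season") <- season
  class(out) <- c("base_season_table", "data.frame")
  out
}

#' Published Texas base effort and landings (2009-2010 seasons)
#'
#' The per-bay average private-boat trips and landings of red drum and spotted
#' seatrout per season from the Texas Marine Sport-Harvest Monitoring Program,
#' used as the calibration anchor of the demand model.
#'
#' @return A list with `high` and `low` [base_season_table()] entries.
#' @export
texas_base_tables <- function() {
  list(
    high = base_season_table(
      "high",
      trips = c(191165, 75973, 57864, 92666, 62542, 83636, 68104),
      harvest_red_drum = c(30997, 13471, 14321, 14930, 13898, 19488, 17097),
      harvest_seatrout = c(104042, 54118, 28796, 20811, 20298, 76372, 56830)),
    low = base_season_table(
      "low",
      trips = c(50761, 29020, 19232, 52620, 35516, 40916, 33185),
      harvest_red_drum = c(7243, 5575, 5035, 8461, 5655, 4143, 6050),
      harvest_seatrout = c(17865, 10406, 12892, 16045, 6746, 18537, 15154))
  )
}

#' Published periodic VARM estimates for the Texas bays
#'
#' The BIC-selected state-space model specifications and maximum-likelihood
#' estimates for each species, as published. Used as realistic defaults for
#' the synthetic generators and for scenario simulation without refitting.
#'
#' @param species `"red_drum"` or `"spotted_seatrout"`.
#' @return A list with elements `spec` ([varm_spec()]) and `params` (named
#'   coefficient vector).
#' @export
texas_varm_params <- function(species = c("red_drum", "spotted_seatrout")) {
  species <- match.arg(species)
  if (species == "red_drum") {
    params <- c(b2_1 = 0.33, w1_1 = 0.27, w3_1 = 0.66, w4_1 = 0.42, v1 = 0.66,
                b2_2 = 0.23, w1_2 = 0.18, w2_2 = 0.28, w3_2 = 0.74, v2 = 0.34)
  } else {
    params <- c(b2_1 = 0.91, w1_1 = 0.12, w2_1 = 0.17, w3_1 = 0.13,
                w4_1 = 0.16, w5_1 = 0.14, v1 = 0.45,
                b1_2 = 0.61, b2_2 = -0.29, w1_2 = 0.21, w2_2 = 0.25,
                w3_2 = 0.14, w4_2 = 0.39, v2 = 0.41)
  }
  list(spec = varm_spec(names(params)), params = params)
}

# internal: seeded substream derivation so adding one noise component does not
# shift the draws of another. Simple string hash folded into [0, 2^31).
substream_seed <- function(seed, name) {
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}
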
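#' Synthetic generator configuration
#'
#' Settings for the trended-CPUE generator. Defaults mirror the study shape
#' (35 years, 7 bays, two seasons) with per-bay log-scale polynomial trends
#' and a stationary fluctuation drawn from the published red-drum periodic
#' VARM estimates (moderately persistent dynamics whose stationarity is
#' detectable at the study's series length).
#'
#' @param years number of years.
#' @param n_bays number of bays.
#' @param base_log_cpue per-bay baseline log CPUE (fish per net-hour).
#' @param trend_slope per-bay linear trend on the log scale, per year.
#' @param trend_quad per-bay quadratic trend coefficient (per year^2).
#' @param varm published-style VARM spec/params list (default
#'   [texas_varm_params()] for red drum).
#' @param fluct_scale multiplier on the stationary component.
#' @return a `synth_config` list.
#' @export
synth_config <- function(years = 35L, n_bays = 7L,
                         base_log_cpue = log(0.2) + seq(-0.3, 0.3,
                                                        length.out = n_bays),
                         trend_slope = rep(c(0.07, -0.05, 0.06, 0.05, 0,
                                             0.08, -0.06),
                                           length.out = n_bays),
                         trend_quad = rep(0, length.out = n_bays),
                         varm = texas_varm_params("red_drum"),
                         fluct_scale = 0.4) {
  stopifnot(years >= 4L, n_bays >= 3L)
  structure(list(years = as.integer(years), n_bays = as.integer(n_bays),
                 base_log_cpue = rep_len(base_log_cpue, n_bays),
                 trend_slope = rep_len(trend_slope, n_bays),
                 trend_quad = rep_len(trend_quad, n_bays),
                 varm = varm, fluct_scale = fluct_scale),
            class = "synth_config")
}

#' Generate a trended raw CPUE data set
#'
#' For each species, bay and season: raw CPUE = exp(polynomial trend +
#' stationary VARM fluctuation), strictly positive and deterministic given
#' the seed. Trend noise and process/observation noise come from named
#' substreams of the master seed, so adding one component does not shift the
#' draws of another.
#'
#' @param config a [synth_config()].
#' @param seed master integer seed.
#' @param species species tags to generate (default both).
#' @return long data frame (`year`, `season`, `bay`, `species`, `cpue`) in
#'   the layout [read_cpue_csv()] reads.
#' @export
gen_trended_cpue <- function(config = synth_config(), seed = 1L,
                             species = species_codes()) {
  J <- config$n_bays
  n <- config$years
  bays <- if (J == 7L) bay_codes() else paste0("B", seq_len(J))
  spec <- config$varm$spec
  if (attr(spec, "n_bays") != J)
    spec <- varm_spec(names(spec)[spec], n_bays = J)
  system <- build_system(spec, config$varm$params)
  out <- list()
  for (sp in species) {
    x <- simulate_varm_system(system, n_steps = 2L * n, burn_in = 100L,
                              seed = substream_seed(seed, paste0("varm_", sp)))
    tau <- seq_len(n)
    for (j in seq_len(J)) {
      trend <- config$base_log_cpue[j] + config$trend_slope[j] * tau +
        config$trend_quad[j] * tau^2
      for (ss in c("spring", "fall")) {
        rows <- if (ss == "spring") seq(1L, 2L * n, by = 2L) else
          seq(2L, 2L * n, by = 2L)
        cpue <- exp(trend + config$fluct_scale * unclass(x)[rows, j])
        out[[length(out) + 1L]] <- data.frame(
          year = 1981L + tau, season = ss, bay = bays[j], species = sp,
          cpue = cpue, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Generate a standardized panel directly from VARM parameters
#'
#' Exact seeded draw from the periodic state-space model, used by the
#' parameter-recovery and model-selection experiments.
#'
#' @param spec a [varm_spec()].
#' @param params named coefficient values for the included coefficients.
#' @param n_steps emitted rows.
#' @param seed integer seed.
#' @param burn_in discarded initial steps.
#' @return a standardized [cpue_panel()].
#' @export
gen_varm_panel <- function(spec, params, n_steps = 70L, seed = 1L,
                           burn_in = 100L) {
  simulate_varm_system(build_system(spec, params), n_steps = n_steps,
                       burn_in = burn_in, seed = seed)
}

#' Generate synthetic conditional-logit choice records
#'
#' Each record perturbs the per-site distances and expected catches around
#' the supplied site table, then samples the chosen site from the logit
#' probabilities. Deterministic given the seed.
#'
#' @param coefs true [choice_coefs()].
#' @param sites data frame with columns `bay`, `distance`, `catch_red`,
#'   `catch_trout` (at least 2 rows).
#' @param n_records number of choice records.
#' @param seed integer seed.
#' @param distance_sd,catch_sd standard deviations of the per-record
#'   perturbations (catches truncated at 0).
#' @return data frame in the [fit_site_choice()] layout: `record`, `bay`,
#'   `distance`, `catch_red`, `catch_trout`, `chosen`.
#' @export
gen_choice_dataset <- function(coefs, sites, n_records = 1000L, seed = 1L,
                               distance_sd = 15, catch_sd = 0.3) {
  stopifnot(nrow(sites) >= 2L)
  set.seed(substream_seed(seed, "choices"))
  J <- nrow(sites)
  out <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    d <- pmax(sites$distance + stats::rnorm(J, 0, distance_sd), 1)
    cr <- pmax(sites$catch_red + stats::rnorm(J, 0, catch_sd), 0)
    ct <- pmax(sites$catch_trout + stats::rnorm(J, 0, catch_sd), 0)
    p <- site_choice_probs(cr, ct, d, coefs)
    pick <- sample.int(J, 1L, prob = p)
    out[[r]] <- data.frame(record = r, bay = sites$bay,
                           distance = d, catch_red = cr, catch_trout = ct,
                           chosen = seq_len(J) == pick,
                           stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Default site table for choice-data generation
#'
#' Seven bays at the high-season calibrated distances and base catch rates.
#'
#' @param base optional [base_season_table()] (default published high
#'   season).
#' @param coefs a [choice_coefs()].
#' @return data frame with `bay`, `distance`, `catch_red`, `catch_trout`.
#' @export
default_choice_sites <- function(base = texas_base_tables()$high,
                                 coefs = choice_coefs()) {
  rates <- base_catch_rates(base)
  data.frame(bay = base$bay,
             distance = as.numeric(calibrate_distances(base, coefs)),
             catch_red = rates$red_drum, catch_trout = rates$spotted_seatrout,
             stringsAsFactors = FALSE)
}
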
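#' Seasonal CPUE panel
#'
#' Container for the time-by-bay catch-per-unit-effort matrix the state-space
#' model consumes: rows alternate spring and fall (starting with spring, time
#' index t = 1, 1.5, ..., in half-year steps), columns are the bays in coastal
#' order. The `stage` tag records where the panel sits in the transformation
#' pipeline: `raw` CPUE, `detrended` (residual plus series mean), or
#' `standardized` (log then per-column z-score).
#'
#' @param values numeric matrix, time by bays.
#' @param stage one of `"raw"`, `"detrended"`, `"standardized"`.
#' @param species species tag carried along for labelling.
#' @param bays column names; defaults to [bay_codes()] when there are 7
#'   columns.
#' @return A `cpue_panel`: the matrix with `stage`, `species` and `t`
#'   attributes.
#' @export
cpue_panel <- function(values, stage = c("raw", "detrended", "standardized"),
                       species = NA_character_, bays = NULL) {
  stage <- match.arg(stage)
  values <- as.matrix(values)
  if (is.null(bays)) {
    bays <- if (ncol(values) == 7L) bay_codes() else
      paste0("B", seq_len(ncol(values)))
  }
  stopifnot(length(bays) == ncol(values))
  if (stage != "standardized" && any(values < 0, na.rm = TRUE))
    stop("raw and detrended CPUE panels must be non-negative")
  dimnames(values) <- list(NULL, bays)
  structure(values, stage = stage, species = species,
            t = seq(1, by = 0.5, length.out = nrow(values)),
            class = c("cpue_panel", "matrix", "array"))
}

panel_stage <- function(panel) attr(panel, "stage")

#' @export
print.cpue_panel <- function(x, ...) {
  cat(sprintf("Seasonal CPUE panel (%s): %d time steps x %d bays, species %s\n",
              attr(x, "stage"), nrow(x), ncol(x), attr(x, "species")))
  n <- min(4L, nrow(x))
  print(round(unclass(x)[seq_len(n), , drop = FALSE], 4))
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Seasons of the panel rows
#'
#' Odd rows are spring, even rows fall (rows alternate starting with spring).
#'
#' @param panel a [cpue_panel()] or row count.
#' @return character vector of `"spring"`/`"fall"` per row.
#' @export
panel_seasons <- function(panel) {
  n <- if (is.matrix(panel)) nrow(panel) else as.integer(panel)
  ifelse(seq_len(n) %% 2L == 1L, "spring", "fall")
}

#' Select the polynomial trend order by leave-one-out cross-validation
#'
#' Fits ordinary-least-squares polynomials in the time index for each
#' candidate degree and scores them by the mean squared leave-one-out
#' prediction error (computed exactly through the hat matrix). Ties go to the
#' smaller order.
#'
#' @param values numeric series (one bay, one season, one species).
#' @param candidate_orders integer degrees to consider; default 0:3 (constant
#'   up to cubic).
#' @return A `trend_fit` list: `order`, `coefficients` (intercept-first, of
#'   the winning OLS fit on the full series), `loocv_mse` (named per
#'   candidate), `t` (the time regressor used).
#' @export
select_poly_order <- function(values, candidate_orders = 0:3) {
  values <- as.numeric(values)
  candidate_orders <- sort(unique(as.integer(candidate_orders)))
  n <- length(values)
  min_len <- max(candidate_orders) + 2L
  if (n < min_len)
    stop(sprintf("series of length %d is too short: need at least %d points",
                 n, min_len))
  if (any(!is.finite(values))) stop("series values must be finite")
  tt <- seq_len(n)
  mse <- vapply(candidate_orders, function(p) {
    X <- stats::poly(tt, degree = max(p, 1L), raw = TRUE)
    X <- cbind(1, X[, seq_len(p), drop = FALSE])
    fit <- stats::lm.fit(X, values)
    h <- rowSums(qr.Q(fit$qr)[, seq_len(fit$rank), drop = FALSE]^2)
    loo <- fit$residuals / (1 - h)
    if (any(h > 1 - 1e-10)) Inf else mean(loo^2)
  }, numeric(1))
  names(mse) <- as.character(candidate_orders)
  best <- candidate_orders[which.min(mse)]   # first minimum = smallest order
  X <- cbind(1, stats::poly(tt, degree = max(best, 1L),
                            raw = TRUE)[, seq_len(best), drop = FALSE])
  coefs <- stats::lm.fit(X, values)$coefficients
  structure(list(order = best, coefficients = unname(coefs),
                 loocv_mse = mse, t = tt),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("Polynomial trend fit: order %d (LOOCV MSE %.4g)\n",
              x$order, x$loocv_mse[as.character(x$order)]))
  invisible(x)
}

#' De-trend a seasonal series
#'
#' Removes the fitted polynomial trend and re-centres the residuals on the
#' series mean, so the de-trended series is a stationary fluctuation around
#' the long-run average CPUE. The operation is mean-preserving.
#'
#' @param values the series the trend was fitted to.
#' @param trend a `trend_fit` from [select_poly_order()].
#' @return numeric series: residual + mean(values).
#' @export
detrend_series <- function(values, trend) {
  values <- as.numeric(values)
  if (length(values) != length(trend$t))
    stop("'trend' was fitted to a series of a different length")
  p <- trend$order
  X <- cbind(1, stats::poly(trend$t, degree = max(p, 1L),
                            raw = TRUE)[, seq_len(p), drop = FALSE])
  fitted <- drop(X %*% trend$coefficients)
  values - fitted + mean(values)
}

#' Assemble a de-trended seasonal panel from long-format CPUE data
#'
#' For one species, de-trends every bay-by-season series separately (order
#' chosen by LOOCV), then interleaves spring and fall into the alternating
#' time-by-bay panel.
#'
#' @param df long data frame with columns `year`, `season`, `bay`, `species`,
#'   `cpue` (as read by [read_cpue_csv()]).
#' @param species which species to extract.
#' @param candidate_orders passed to [select_poly_order()].
#' @return list: `panel` (a detrended [cpue_panel()]), `trends` (per
#'   bay/season `trend_fit`s), `raw` (the raw panel).
#' @export
build_detrended_panel <- function(df, species, candidate_orders = 0:3) {
  df <- df[df$species == species, , drop = FALSE]
  if (nrow(df) == 0L) stop("no rows for species ", species)
  bays <- bay_codes()[bay_codes() %in% unique(df$bay)]
  if (length(bays) == 0L) { bays <- sort(unique(df$bay)) }
  years <- sort(unique(df$year))
  n <- length(years)
  raw <- det <- matrix(NA_real_, nrow = 2L * n, ncol = length(bays),
                       dimnames = list(NULL, bays))
  trends <- list()
  for (b in bays) {
    for (ss in c("spring", "fall")) {
      sub <- df[df$bay == b & df$season == ss, , drop = FALSE]
      sub <- sub[order(sub$year), , drop = FALSE]
      if (!identical(sub$year, years))
        stop(sprintf("series %s/%s has missing or extra years", b, ss))
      rows <- if (ss == "spring") seq(1L, 2L * n, by = 2L) else
        seq(2L, 2L * n, by = 2L)
      fit <- select_poly_order(sub$cpue, candidate_orders)
      raw[rows, b] <- sub$cpue
      det[rows, b] <- detrend_series(sub$cpue, fit)
      trends[[paste(b, ss, sep = ".")]] <- fit
    }
  }
  det[det < 0] <- 0   # de-trending can undershoot; CPUE floor handled at log stage
  list(panel = cpue_panel(det, "detrended", species, bays),
       trends = trends,
       raw = cpue_panel(raw, "raw", species, bays))
}

#' Standardize a de-trended panel for state-space fitting
#'
#' Takes the natural log of each cell (after flooring at a small fraction of
#' the column mean, since de-trended values can touch zero) and z-scores each
#' bay column, so every column has mean 0 and standard deviation 1. The
#' returned transform inverts the operation for simulated output.
#'
#' @param panel a `detrended` [cpue_panel()].
#' @param floor_frac floor applied before logging, as a fraction of the column
#'   mean; default 1e-3.
#' @return list: `panel` (standardized [cpue_panel()]), `transform` (class
#'   `standardize_transform` with per-column log means/sds and floors).
#' @export
standardize_panel <- function(panel, floor_frac = 1e-3) {
  if (!identical(panel_stage(panel), "detrended"))
    stop("'panel' must be at the 'detrended' stage")
  v <- unclass(panel)
  mu <- colMeans(v, na.rm = TRUE)
  if (any(mu <= 0)) stop("every bay column must have a positive mean CPUE")
  floors <- floor_frac * mu
  lv <- log(pmax(sweep(v, 2, 0, "+"), rep(floors, each = nrow(v))))
  m <- colMeans(lv, na.rm = TRUE)
  s <- apply(lv, 2, stats::sd, na.rm = TRUE)
  if (any(s <= 1e-12))
    stop("zero variance after logging in column(s): ",
         paste(colnames(v)[s <= 1e-12], collapse = ", "))
  z <- sweep(sweep(lv, 2, m, "-"), 2, s, "/")
  transform <- structure(list(log_mean = m, log_sd = s, floor = floors),
                         class = "standardize_transform")
  list(panel = cpue_panel(z, "standardized", attr(panel, "species"),
                          colnames(v)),
       transform = transform)
}

#' Invert the log/z-score standardization
#'
#' Maps a standardized panel (e.g. simulated model output) back to the
#' positive CPUE scale: cell = exp(z * sd + mean) per column.
#'
#' @param panel a `standardized` [cpue_panel()].
#' @param transform the `standardize_transform` from [standardize_panel()].
#' @return a `detrended` [cpue_panel()], strictly positive.
#' @export
unstandardize_panel <- function(panel, transform) {
  if (!identical(panel_stage(panel), "standardized"))
    stop("'panel' must be at the 'standardized' stage")
  if (ncol(panel) != length(transform$log_mean))
    stop("transform dimensions do not match the panel")
  z <- unclass(panel)
  v <- exp(sweep(sweep(z, 2, transform$log_sd, "*"), 2,
                 transform$log_mean, "+"))
  cpue_panel(v, "detrended", attr(panel, "species"), colnames(panel))
}

#' Identity standardize transform
#'
#' A neutral transform (log-mean 0, log-sd 1) for simulations that live
#' directly on the standardized scale: unstandardizing with it simply
#' exponentiates.
#'
#' @param n_bays number of columns.
#' @return a `standardize_transform`.
#' @export
identity_transform <- function(n_bays = 7L) {
  structure(list(log_mean = rep(0, n_bays), log_sd = rep(1, n_bays),
                 floor = rep(1e-3, n_bays)),
            class = "standardize_transform")
}
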
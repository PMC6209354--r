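#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root screen for the de-trended seasonal series. The test regression
#' includes a constant but no deterministic trend (the series are de-trended
#' before testing): Δy_t = c + ρ y_{t-1} + Σ φ_i Δy_{t-i} + e_t. The
#' augmentation lag is chosen by AIC over 0..`max_lag` on a common estimation
#' sample, then the statistic is computed from a refit of the chosen lag on
#' its maximal sample. The null of a unit root is rejected when the t-ratio
#' on ρ falls below the MacKinnon (2010) finite-sample critical value.
#'
#' @param values numeric series.
#' @param max_lag maximum augmentation lag (default 3).
#' @param alpha test level: one of 0.01, 0.05, 0.1 (default 0.1).
#' @return list: `stationary` (logical; TRUE means the unit-root null is
#'   rejected), `statistic`, `chosen_lag`, `critical_value`, `alpha`.
#' @export
adf_stationary <- function(values, max_lag = 3L, alpha = 0.1) {
  values <- as.numeric(values)
  n <- length(values)
  max_lag <- as.integer(max_lag)
  if (n <= max_lag + 3L)
    stop(sprintf("series length %d too short for max_lag %d", n, max_lag))
  if (stats::sd(values) < 1e-12)
    stop("ADF test is undefined for a constant series")
  dy <- diff(values)
  # common estimation sample across candidate lags for AIC comparability
  aic <- vapply(0:max_lag, function(p) {
    fit <- adf_regression(values, dy, p, start = max_lag + 2L)
    ne <- length(fit$residuals)
    ne * log(sum(fit$residuals^2) / ne) + 2 * (p + 2)
  }, numeric(1))
  p <- (0:max_lag)[which.min(aic)]
  fit <- adf_regression(values, dy, p, start = p + 2L)
  rho <- fit$coefficients[2L]
  ne <- length(fit$residuals)
  k <- length(fit$coefficients)
  sigma2 <- sum(fit$residuals^2) / (ne - k)
  XtX_inv <- chol2inv(chol(crossprod(fit$X)))
  se <- sqrt(sigma2 * XtX_inv[2L, 2L])
  stat <- unname(rho / se)
  cv <- adf_critical_value(alpha, ne)
  list(stationary = stat < cv, statistic = stat, chosen_lag = p,
       critical_value = cv, alpha = alpha)
}

# Δy_i on [1, y_{i-1}, Δy_{i-1..i-p}] for i = start..n (in levels indexing)
adf_regression <- function(y, dy, p, start) {
  n <- length(y)
  idx <- start:n
  X <- cbind(1, y[idx - 1L])
  if (p > 0L) for (i in seq_len(p)) X <- cbind(X, dy[idx - 1L - i])
  fit <- stats::lm.fit(X, dy[idx - 1L])
  fit$X <- X
  fit
}

# MacKinnon (2010) response-surface critical values for the
# constant-no-trend Dickey-Fuller t distribution.
adf_critical_value <- function(alpha, n) {
  tab <- list(`0.01` = c(-3.43035, -6.5393, -16.786, -79.433),
              `0.05` = c(-2.86154, -2.8903, -4.234, -40.040),
              `0.1`  = c(-2.56677, -1.5384, -2.809, 0))
  key <- as.character(alpha)
  if (!key %in% names(tab))
    stop("alpha must be one of 0.01, 0.05, 0.1")
  b <- tab[[key]]
  b[1] + b[2] / n + b[3] / n^2 + b[4] / n^3
}

#' Stationarity screen over every series of a study-shaped data set
#'
#' Runs [adf_stationary()] over each species-by-bay-by-season series of a
#' long-format CPUE table (28 series for 2 species x 7 bays x 2 seasons).
#'
#' @param df long CPUE data frame (`year`, `season`, `bay`, `species`,
#'   `cpue`).
#' @param max_lag,alpha passed to [adf_stationary()].
#' @return data frame with one row per series: `species`, `bay`, `season`,
#'   `stationary`, `statistic`, `chosen_lag`.
#' @export
adf_screen <- function(df, max_lag = 3L, alpha = 0.1) {
  keys <- unique(df[, c("species", "bay", "season")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    k <- keys[i, ]
    sub <- df[df$species == k$species & df$bay == k$bay &
                df$season == k$season, ]
    sub <- sub[order(sub$year), ]
    v <- adf_stationary(sub$cpue, max_lag, alpha)
    data.frame(k, stationary = v$stationary, statistic = v$statistic,
               chosen_lag = v$chosen_lag, row.names = NULL)
  })
  do.call(rbind, res)
}
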
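#' Exact Gaussian log-likelihood of a standardized panel
#'
#' Runs the periodic Kalman filter over the alternating spring/fall rows of a
#' standardized panel and returns the exact Gaussian log-likelihood of the
#' observations under the state-space model. The initial state is drawn from
#' the stationary distribution of the composite two-season map (discrete
#' Lyapunov equation); a diffuse prior (variance `diffuse_var`) is available
#' for non-stationary dynamics. Missing cells are skipped in the update.
#'
#' @param system a `varm_system` from [build_system()].
#' @param panel a standardized [cpue_panel()] (or plain matrix) with rows
#'   alternating spring/fall, columns matching `system$n_bays`.
#' @param init `"stationary"` (default) or `"diffuse"`.
#' @param diffuse_var prior state variance under diffuse initialization.
#' @return the log-likelihood (scalar).
#' @export
kalman_loglik <- function(system, panel, init = c("stationary", "diffuse"),
                          diffuse_var = 1e7) {
  init <- match.arg(init)
  y <- unclass(panel)
  if (ncol(y) != system$n_bays)
    stop("panel has ", ncol(y), " columns but the system expects ",
         system$n_bays)
  P0 <- if (init == "stationary") stationary_covariance(system) else
    diag(diffuse_var, 2L * system$n_bays)
  out <- kalman_filter_cpp(y, system$A[[1]], system$A[[2]],
                           system$Q[[1]], system$Q[[2]],
                           system$v[1], system$v[2], P0, FALSE)
  out$loglik
}

# filter pass returning standardized one-step-ahead innovations
kalman_innovations <- function(system, panel, init = "stationary",
                               diffuse_var = 1e7) {
  y <- unclass(panel)
  P0 <- if (init == "stationary") stationary_covariance(system) else
    diag(diffuse_var, 2L * system$n_bays)
  out <- kalman_filter_cpp(y, system$A[[1]], system$A[[2]],
                           system$Q[[1]], system$Q[[2]],
                           system$v[1], system$v[2], P0, TRUE)
  out
}

#' Simulate a standardized panel from the periodic model
#'
#' Draws process and observation shocks i.i.d. standard normal, starts the
#' state from its stationary distribution, iterates the two-season recursion
#' (discarding `burn_in` initial steps) and emits observations
#' y_t = x_t + v_s e_t. Deterministic given the seed.
#'
#' @param system a `varm_system`.
#' @param n_steps number of emitted rows (default 70 = 35 years x 2 seasons).
#' @param burn_in discarded initial steps (default 100).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a standardized [cpue_panel()].
#' @export
simulate_varm_system <- function(system, n_steps = 70L, burn_in = 100L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  burn_in <- 2L * as.integer(ceiling(burn_in / 2))  # keep emitted rows spring-first
  J <- system$n_bays
  P0 <- stationary_covariance(system)   # errors if dynamics are explosive
  n <- 2L * J
  ev <- eigen(P0, symmetric = TRUE)
  rt <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), n) %*% t(ev$vectors)
  z <- drop(rt %*% stats::rnorm(n))
  total <- burn_in + n_steps
  eps <- matrix(stats::rnorm(total * J), total, J)
  obs <- matrix(stats::rnorm(total * J), total, J)
  y <- matrix(NA_real_, n_steps, J)
  for (r in seq_len(total)) {
    s <- if (r %% 2L == 1L) 1L else 2L
    if (r > 1L)
      z <- drop(system$A[[s]] %*% z) +
        c(drop(system$W[[s]] %*% eps[r, ]), rep(0, J))
    if (r > burn_in)
      y[r - burn_in, ] <- z[seq_len(J)] + system$v[s] * obs[r, ]
  }
  cpue_panel(y, "standardized", bays = if (J == 7L) bay_codes() else NULL)
}
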
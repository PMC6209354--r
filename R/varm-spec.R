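#' Coefficient names of the periodic VARM
#'
#' The 16 named coefficients of the two-season model: per season s (1 =
#' spring, 2 = fall) the autoregressive terms `b1_s` (half-year lag) and
#' `b2_s` (one-year lag), the five process-error loadings `w1_s`..`w5_s`
#' (neighbour offsets j-2..j+2, own bay at `w3_s`), and the observation-error
#' scale `v s`.
#'
#' @return character vector of 16 names in canonical order.
#' @export
varm_coef_names <- function() {
  c("b1_1", "b2_1", paste0("w", 1:5, "_1"), "v1",
    "b1_2", "b2_2", paste0("w", 1:5, "_2"), "v2")
}

varm_mandatory <- function() c("w4_1", "w4_2", "v1", "v2")

#' Periodic VARM specification
#'
#' A model specification is an inclusion mask over the 16 coefficients:
#' excluded coefficients are fixed to zero. Note the mandatory set used in
#' model enumeration is literally \{v1, v2, w4_1, w4_2\} — the j+1-neighbour
#' process loading, not the own-bay w3 — matching the published model space.
#'
#' @param include character vector of included coefficient names (subset of
#'   [varm_coef_names()]).
#' @param n_bays number of bays (columns); default 7.
#' @return A `varm_spec`: named logical inclusion vector with an `n_bays`
#'   attribute.
#' @export
varm_spec <- function(include, n_bays = 7L) {
  nm <- varm_coef_names()
  include <- as.character(include)
  bad <- setdiff(include, nm)
  if (length(bad))
    stop("unknown coefficient name(s): ", paste(bad, collapse = ", "))
  mask <- stats::setNames(nm %in% include, nm)
  structure(mask, n_bays = as.integer(n_bays), class = "varm_spec")
}

#' @export
print.varm_spec <- function(x, ...) {
  cat("Periodic VARM spec (", sum(x), " of 16 coefficients):\n  ",
      paste(names(x)[x], collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Enumerate the nested candidate model space
#'
#' All specifications that include the four mandatory coefficients (v1, v2,
#' w4_1, w4_2) and a proper subset of the remaining optional coefficients —
#' at least one optional coefficient excluded — giving 2^n - 1 candidates
#' (4095 for the full 12 optional coefficients).
#'
#' @param n_optional number of optional coefficients to enumerate over,
#'   counted from the front of the canonical optional ordering; default 12
#'   (all of them).
#' @param n_bays passed to [varm_spec()].
#' @return list of `varm_spec` objects, duplicate-free.
#' @export
enumerate_varm_specs <- function(n_optional = 12L, n_bays = 7L) {
  n_optional <- as.integer(n_optional)
  optional <- setdiff(varm_coef_names(), varm_mandatory())
  if (n_optional < 1L || n_optional > length(optional))
    stop("n_optional must be between 1 and ", length(optional))
  optional <- optional[seq_len(n_optional)]
  out <- vector("list", 2L^n_optional - 1L)
  k <- 0L
  for (code in 0:(2L^n_optional - 2L)) {   # all-included (2^n - 1) excluded
    sel <- optional[bitwAnd(code, bitwShiftL(1L, seq_len(n_optional) - 1L)) > 0L]
    k <- k + 1L
    out[[k]] <- varm_spec(c(varm_mandatory(), sel), n_bays)
  }
  out
}

#' Banded process-noise loading matrix for one season
#'
#' Row j of W_s carries the loadings of the bay-j state on the unit-variance
#' process shocks of bays j-2..j+2: `w1_s` at column j-2 through `w5_s` at
#' column j+2, with structural zeros where the neighbour does not exist
#' (bays at the coastal edges).
#'
#' @param w numeric length-5 vector (excluded coefficients as 0).
#' @param n_bays matrix dimension.
#' @return n_bays x n_bays matrix of bandwidth 2.
#' @export
build_w_matrix <- function(w, n_bays = 7L) {
  stopifnot(length(w) == 5L)
  W <- matrix(0, n_bays, n_bays)
  for (j in seq_len(n_bays)) {
    for (k in 1:5) {
      col <- j + k - 3L
      if (col >= 1L && col <= n_bays) W[j, col] <- w[k]
    }
  }
  W
}

#' Assemble the periodic state-space system
#'
#' Builds, for each season s, the transition of the stacked state
#' z_t = \[x_t; x_{t-0.5}\] (dimension 2J): x advances by
#' x_t = b1_s x_{t-0.5} + b2_s x_{t-1} + W_s eps with eps ~ N(0, I), and the
#' observation is y_t = x_t + v_s e_t with e ~ N(0, I). Season indexing
#' follows the target row: spring rows use the s = 1 coefficients.
#'
#' @param spec a [varm_spec()].
#' @param params named numeric vector covering exactly the included
#'   coefficients.
#' @return A `varm_system` list: `A` (list of two 2Jx2J transition matrices),
#'   `Q` (process-noise covariances), `W` (JxJ loading matrices), `v`
#'   (observation scales), `n_bays`, `spec`, `params`.
#' @export
build_system <- function(spec, params) {
  stopifnot(inherits(spec, "varm_spec"))
  J <- attr(spec, "n_bays")
  incl <- names(spec)[spec]
  if (!setequal(names(params), incl))
    stop("'params' must cover exactly the included coefficients; expected {",
         paste(incl, collapse = ", "), "}")
  full <- stats::setNames(numeric(16L), varm_coef_names())
  full[names(params)] <- params
  if (any(full[c("v1", "v2")] < 0) || any(full[grep("^w", names(full))] < 0))
    stop("w and v coefficients must be non-negative")
  A <- Q <- W <- vector("list", 2L)
  for (s in 1:2) {
    b1 <- full[sprintf("b1_%d", s)]
    b2 <- full[sprintf("b2_%d", s)]
    Ws <- build_w_matrix(full[sprintf("w%d_%d", 1:5, s)], J)
    As <- matrix(0, 2L * J, 2L * J)
    As[seq_len(J), seq_len(J)] <- diag(b1, J)
    As[seq_len(J), J + seq_len(J)] <- diag(b2, J)
    As[J + seq_len(J), seq_len(J)] <- diag(J)
    Qs <- matrix(0, 2L * J, 2L * J)
    Qs[seq_len(J), seq_len(J)] <- tcrossprod(Ws)
    A[[s]] <- As; Q[[s]] <- Qs; W[[s]] <- Ws
  }
  structure(list(A = A, Q = Q, W = W,
                 v = unname(full[c("v1", "v2")]),
                 n_bays = J, spec = spec, params = full[spec]),
            class = "varm_system")
}

# stationary covariance of the stacked state at the spring phase:
# z_spr = A1 A2 z_spr_prev + A1 eta2 + eta1, solved as a discrete Lyapunov
# equation by vectorization. Errors when the composite map is explosive.
stationary_covariance <- function(system) {
  Ac <- system$A[[1]] %*% system$A[[2]]
  Qc <- system$A[[1]] %*% system$Q[[2]] %*% t(system$A[[1]]) + system$Q[[1]]
  sr <- max(Mod(eigen(Ac, only.values = TRUE)$values))
  if (sr >= 1 - 1e-8)
    stop("composite seasonal map is non-stationary (spectral radius ",
         sprintf("%.3f", sr), "); use diffuse initialization")
  n <- nrow(Ac)
  P <- matrix(solve(diag(n^2) - kronecker(Ac, Ac), as.vector(Qc)), n, n)
  (P + t(P)) / 2
}
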
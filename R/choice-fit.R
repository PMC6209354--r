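#' Estimate site-choice coefficients by conditional-logit maximum likelihood
#'
#' Fits the three utility coefficients (distance, expected red drum catch,
#' expected seatrout catch) to choice records by maximizing the
#' conditional-logit log-likelihood: the sum over records of the log
#' probability of the chosen site. Standard errors come from the inverse
#' observed information at the optimum.
#'
#' @param records data frame with one row per record-alternative: columns
#'   `record` (record id), `distance`, `catch_red`, `catch_trout`, `chosen`
#'   (exactly one TRUE/1 per record). Every record needs at least two
#'   alternatives; at least 50 records are required.
#' @param start optional starting values (beta_d, beta_cR, beta_cS).
#' @return An object of class `site_choice_fit` with `coefficients`, `se`,
#'   `vcov`, `loglik`, `n_records`, plus `print`/`coef`/`summary`/`vcov`
#'   methods.
#' @export
fit_site_choice <- function(records, start = c(-0.05, 0.1, 0.1)) {
  need <- c("record", "distance", "catch_red", "catch_trout", "chosen")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records is missing column(s): ",
                         paste(miss, collapse = ", "))
  grp <- factor(records$record, levels = unique(records$record))
  n_alt <- table(grp)
  if (any(n_alt < 2L)) stop("every record needs at least 2 alternatives")
  if (nlevels(grp) < 50L) stop("need at least 50 choice records, got ",
                               nlevels(grp))
  chosen <- as.logical(records$chosen)
  if (!all(tapply(chosen, grp, sum) == 1L))
    stop("each record must have exactly one chosen alternative")
  X <- cbind(records$distance, records$catch_red, records$catch_trout)
  colnames(X) <- c("beta_d", "beta_cR", "beta_cS")
  # within-record variation is required for identification
  demeaned <- X - apply(X, 2, function(col) ave(col, grp))
  novar <- apply(demeaned, 2, function(col) all(abs(col) < 1e-12))
  if (any(novar))
    stop("no within-record variation in: ",
         paste(colnames(X)[novar], collapse = ", "),
         "; coefficient(s) not estimable")
  gidx <- as.integer(grp)

  negll <- function(theta) {
    u <- drop(X %*% theta)
    mg <- tapply(u, gidx, max)
    lse <- mg + log(tapply(exp(u - mg[gidx]), gidx, sum))
    -(sum(u[chosen]) - sum(lse))
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-12))
  if (opt$convergence != 0)
    stop("conditional-logit optimization failed to converge")
  H <- stats::optimHess(opt$par, negll)
  V <- tryCatch(solve(H), error = function(e)
    stop("observed information is singular: coefficients not estimable"))
  if (any(!is.finite(diag(V))) || any(diag(V) <= 0))
    stop("observed information is singular: coefficients not estimable")
  est <- stats::setNames(opt$par, colnames(X))
  dimnames(V) <- list(names(est), names(est))
  structure(list(coefficients = est, se = sqrt(diag(V)), vcov = V,
                 loglik = -opt$value, n_records = nlevels(grp)),
            class = "site_choice_fit")
}

#' @export
print.site_choice_fit <- function(x, ...) {
  cat(sprintf("Conditional-logit site-choice fit (%d records, logLik %.2f)\n",
              x$n_records, x$loglik))
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' @export
coef.site_choice_fit <- function(object, ...) object$coefficients

#' @export
vcov.site_choice_fit <- function(object, ...) object$vcov

#' @export
summary.site_choice_fit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = object$coefficients / object$se)
  stats::printCoefmat(tab, digits = 4)
  invisible(object)
}

#' @export
logLik.site_choice_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_records, class = "logLik")
}
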
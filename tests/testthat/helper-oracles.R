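# Independent oracles used across the suite. These deliberately avoid the
# package's Kalman/optimization code paths: the joint-Gaussian density is
# assembled directly from the linear recursions, and LOOCV is a literal
# leave-one-out loop.

# multivariate normal log-density at zero mean via Cholesky
dmvnorm_log <- function(x, Sigma) {
  L <- chol(Sigma)
  u <- backsolve(L, x, transpose = TRUE)
  -0.5 * (length(x) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(u^2))
}

# brute-force joint Gaussian log-likelihood of a full panel (no NAs):
# stack all states, build their joint covariance from the recursions,
# project to observations, evaluate the density directly.
brute_loglik <- function(system, y) {
  Tn <- nrow(y); J <- ncol(y); n <- 2L * J
  P1 <- baytrips:::stationary_covariance(system)
  As <- lapply(seq_len(Tn), function(r)
    if (r %% 2 == 1) system$A[[1]] else system$A[[2]])
  Qs <- lapply(seq_len(Tn), function(r)
    if (r %% 2 == 1) system$Q[[1]] else system$Q[[2]])
  Ps <- vector("list", Tn)
  Ps[[1]] <- P1
  if (Tn > 1)
    for (r in 2:Tn) Ps[[r]] <- As[[r]] %*% Ps[[r - 1]] %*% t(As[[r]]) + Qs[[r]]
  idx <- function(r) ((r - 1L) * n + 1L):(r * n)
  C <- matrix(0, Tn * n, Tn * n)
  for (r in seq_len(Tn)) {
    C[idx(r), idx(r)] <- Ps[[r]]
    if (r < Tn) {
      M <- Ps[[r]]
      for (q in (r + 1L):Tn) {
        M <- M %*% t(As[[q]])
        C[idx(r), idx(q)] <- M
        C[idx(q), idx(r)] <- t(M)
      }
    }
  }
  Hbig <- matrix(0, Tn * J, Tn * n)
  Rdiag <- numeric(Tn * J)
  for (r in seq_len(Tn)) {
    rows <- ((r - 1L) * J + 1L):(r * J)
    Hbig[cbind(rows, idx(r)[seq_len(J)])] <- 1
    v <- if (r %% 2 == 1) system$v[1] else system$v[2]
    Rdiag[rows] <- v^2
  }
  Sigma <- Hbig %*% C %*% t(Hbig) + diag(Rdiag)
  dmvnorm_log(as.vector(t(y)), Sigma)
}

# literal leave-one-out CV loop over polynomial orders
brute_loocv_order <- function(values, candidate_orders = 0:3) {
  n <- length(values)
  tt <- seq_len(n)
  mse <- sapply(candidate_orders, function(p) {
    errs <- sapply(seq_len(n), function(i) {
      Xi <- cbind(1, stats::poly(tt, degree = max(p, 1), raw = TRUE)[
        , seq_len(p), drop = FALSE])
      fit <- stats::lm.fit(Xi[-i, , drop = FALSE], values[-i])
      values[i] - sum(Xi[i, ] * fit$coefficients)
    })
    mean(errs^2)
  })
  candidate_orders[which.min(mse)]
}

# closed-form stationary covariance of the stacked state at the spring and
# fall phases, via the discrete Lyapunov equation of the composite map
phase_covariances <- function(system) {
  A1 <- system$A[[1]]; A2 <- system$A[[2]]
  Q1 <- system$Q[[1]]; Q2 <- system$Q[[2]]
  Ac <- A1 %*% A2
  Qc <- A1 %*% Q2 %*% t(A1) + Q1
  n <- nrow(Ac)
  P_spring <- matrix(solve(diag(n^2) - kronecker(Ac, Ac), as.vector(Qc)), n, n)
  P_fall <- A2 %*% P_spring %*% t(A2) + Q2
  list(spring = (P_spring + t(P_spring)) / 2, fall = (P_fall + t(P_fall)) / 2)
}

# random small system with stable dynamics, for property tests
random_system <- function(J, seed) {
  set.seed(seed)
  repeat {
    params <- c(b1_1 = runif(1, -0.6, 0.6), b2_1 = runif(1, -0.5, 0.5),
                b1_2 = runif(1, -0.6, 0.6), b2_2 = runif(1, -0.5, 0.5),
                w1_1 = runif(1, 0, 0.5), w2_1 = runif(1, 0, 0.5),
                w3_1 = runif(1, 0.2, 1), w4_1 = runif(1, 0, 0.5),
                w5_1 = runif(1, 0, 0.5),
                w1_2 = runif(1, 0, 0.5), w2_2 = runif(1, 0, 0.5),
                w3_2 = runif(1, 0.2, 1), w4_2 = runif(1, 0, 0.5),
                w5_2 = runif(1, 0, 0.5),
                v1 = runif(1, 0.2, 1), v2 = runif(1, 0.2, 1))
    spec <- varm_spec(names(params), n_bays = J)
    sys <- build_system(spec, params)
    Ac <- sys$A[[1]] %*% sys$A[[2]]
    if (max(Mod(eigen(Ac, only.values = TRUE)$values)) < 0.95) return(sys)
  }
}

table2_high <- function() texas_base_tables()$high
table2_low <- function() texas_base_tables()$low
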
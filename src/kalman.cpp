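// Periodic linear-Gaussian Kalman filter for the two-season bay model.
// State z_t = [x_t; x_{t-0.5}] (2J), observation y_t = x_t + v_s e_t.
// Rows of y alternate seasons starting with season 1 (spring); the
// transition into row r uses the season of row r. NA cells are skipped in
// the update.
//
// For complete panels the predicted covariance cycles to a per-season
// steady state; once it has converged (relative Frobenius change < 1e-13 on
// two consecutive visits) the cached gain and innovation Cholesky are
// reused, which makes long-panel likelihoods cheap without changing the
// result beyond ~1e-10.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export]]
Rcpp::List kalman_filter_cpp(const arma::mat& y,
                             const arma::mat& A1, const arma::mat& A2,
                             const arma::mat& Q1, const arma::mat& Q2,
                             const double v1, const double v2,
                             const arma::mat& P0,
                             const bool want_innovations) {
  const uword T = y.n_rows, J = y.n_cols;
  const double log2pi = std::log(2.0 * M_PI);
  vec z(A1.n_rows, fill::zeros);
  mat P = P0;
  double loglik = 0.0;
  mat innov, innov_sd;
  if (want_innovations) {
    innov.set_size(T, J); innov.fill(datum::nan);
    innov_sd.set_size(T, J); innov_sd.fill(datum::nan);
  }

  const bool complete = y.is_finite();
  mat Pp_prev[2], Lc[2], Kc[2], Ppost[2];
  vec sdc[2];
  double slogdet[2] = {0, 0};
  int n_conv[2] = {0, 0};
  bool have_prev[2] = {false, false}, steady[2] = {false, false};

  for (uword r = 0; r < T; ++r) {
    const int si = (r % 2 == 0) ? 0 : 1;  // phase of row r (first row spring)
    const double v = (si == 0) ? v1 : v2;
    const mat& A = (si == 0) ? A1 : A2;
    const mat& Q = (si == 0) ? Q1 : Q2;

    if (complete && steady[si] && r > 0) {
      z = A * z;
      vec resid = y.row(r).t() - z.head(J);
      vec u = solve(trimatl(Lc[si]), resid);
      loglik += -0.5 * (J * log2pi) - slogdet[si] - 0.5 * dot(u, u);
      z += Kc[si] * resid;
      if (want_innovations) {
        innov.row(r) = resid.t();
        innov_sd.row(r) = sdc[si].t();
      }
      continue;
    }

    if (r > 0) {
      z = A * z;
      P = A * P * A.t() + Q;
      if (complete) {
        if (have_prev[si]) {
          double rel = norm(P - Pp_prev[si], "fro") / (1.0 + norm(P, "fro"));
          n_conv[si] = (rel < 1e-13) ? n_conv[si] + 1 : 0;
        }
        Pp_prev[si] = P;
        have_prev[si] = true;
      }
    }

    uvec obs = find_finite(y.row(r).t());
    if (obs.n_elem == 0) continue;
    mat PH = P.cols(obs);
    mat S = P.submat(obs, obs) + (v * v) * eye(obs.n_elem, obs.n_elem);
    S = 0.5 * (S + S.t());
    mat L;
    if (!chol(L, S, "lower"))
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf);
    vec resid = y.row(r).t();
    resid = resid.elem(obs) - z.elem(obs);
    vec u = solve(trimatl(L), resid);
    double sld = accu(log(L.diag()));
    loglik += -0.5 * (obs.n_elem * log2pi) - sld - 0.5 * dot(u, u);
    mat K = PH * inv_sympd(S);
    z += K * resid;
    P -= K * PH.t();
    P = 0.5 * (P + P.t());
    if (want_innovations) {
      for (uword k = 0; k < obs.n_elem; ++k) {
        innov(r, obs(k)) = resid(k);
        innov_sd(r, obs(k)) = std::sqrt(S(k, k));
      }
    }
    if (complete && r > 0 && n_conv[si] >= 2 && !steady[si]) {
      steady[si] = true;
      Lc[si] = L; Kc[si] = K; Ppost[si] = P; slogdet[si] = sld;
      sdc[si] = sqrt(S.diag());
    }
  }
  if (want_innovations)
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                              Rcpp::Named("innovations") = innov,
                              Rcpp::Named("innovation_sd") = innov_sd);
  return Rcpp::List::create(Rcpp::Named("loglik") = loglik);
}
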
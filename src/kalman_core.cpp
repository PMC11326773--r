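// Kalman filter / RTS smoother for the variational state update of the
// oscillation component model.
//
// The measurement update is done in information form so that the expected
// observation quadratic E[C' R^-1 C] (which includes the second-moment
// correction from the mixing-matrix posterior) enters exactly:
//
//   q(x) \propto p(x) * prod_t exp( -0.5 x_t' G x_t + b_t' x_t - g_t ),
//   G   = E[C' R^-1 C],  b_t = E[C]' E[R^-1] y_t,
//   g_t = L/2 log(2*pi) - 0.5 E[log det R^-1] + 0.5 y_t' E[R^-1] y_t.
//
// The returned log-normalizer logZ = log \int p(x) prod_t exp(...) dx is the
// state-integral contribution to the negative variational free energy; with
// point-mass observation posteriors it reduces to the usual innovations
// log-likelihood.
//
// The model is time-invariant, so the covariance recursions converge to a
// steady state; once successive covariances agree to a tight relative
// tolerance the cached matrices are reused and only the mean recursions are
// propagated. With want_moments = false only the aggregated sufficient
// statistics are returned, avoiding the O(T d^2) moment storage that the
// learning loop does not need.

#include <RcppArmadillo.h>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat symm(const mat& X) { return 0.5 * (X + X.t()); }

static inline double logdet_sympd(const mat& X) {
  mat Lc = chol(X, "lower");
  return 2.0 * sum(log(Lc.diag()));
}

// [[Rcpp::export(name = ".kalman_core")]]
Rcpp::List kalman_core(const arma::mat& y,      // T x L observations
                       const arma::mat& A,      // d x d transition
                       const arma::mat& Q,      // d x d process covariance
                       const arma::mat& P0,     // d x d initial (stationary) cov
                       const arma::vec& m0,     // d initial mean
                       const arma::mat& Cmean,  // L x d expected mixing matrix
                       const arma::mat& G,      // d x d expected C' R^-1 C
                       const arma::mat& Rinv,   // L x L expected noise precision
                       const double logdet_Rinv, // E[log det R^-1]
                       const bool smooth,
                       const bool want_moments) {
  const uword T = y.n_rows, L = y.n_cols, d = A.n_rows;
  const double g_const = 0.5 * L * std::log(2.0 * M_PI) - 0.5 * logdet_Rinv;
  const double ss_tol = 1e-9;

  mat B = Cmean.t() * Rinv;         // d x L, b_t = B y_t
  vec yq(T);                        // y_t' Rinv y_t
  {
    mat YR = y * Rinv;
    for (uword t = 0; t < T; ++t) yq(t) = dot(YR.row(t), y.row(t));
  }

  // Filtered/predicted covariances stored until the steady state kicks in.
  std::vector<mat> PfV, PpV;        // PfV[t] for t = 0..min(t_ss, T);
  PfV.reserve(64); PpV.reserve(64); // PpV[t-1] for t = 1..min(t_ss, T)
  mat  mf(d, T + 1), mp(d, T + 1);
  mf.col(0) = m0;
  PfV.push_back(symm(P0));
  double logZ = 0.0;

  bool ss = false;                  // filter covariances in steady state
  uword t_ss = T + 1;               // first steady-state index
  mat Ppi_c, Pupd_c, Ppred_c;       // cached steady-state matrices
  double ld_diff_c = 0.0;

  auto Pf_at = [&](uword t) -> const mat& {
    return (ss && t >= t_ss) ? Pupd_c : PfV[t];
  };
  auto Pp_at = [&](uword t) -> const mat& {  // t in 1..T
    return (ss && t >= t_ss) ? Ppred_c : PpV[t - 1];
  };

  for (uword t = 1; t <= T; ++t) {
    vec mpred = A * mf.col(t - 1);
    mp.col(t) = mpred;
    vec b = B * y.row(t - 1).t();

    if (!ss) {
      mat Ppred = symm(A * PfV[t - 1] * A.t() + Q);
      mat Ppi = inv_sympd(Ppred);
      mat S = symm(Ppi + G);
      mat Pupd = symm(inv_sympd(S));
      PpV.push_back(Ppred);
      PfV.push_back(Pupd);
      vec eta = Ppi * mpred + b;
      vec mupd = Pupd * eta;
      mf.col(t) = mupd;
      logZ += 0.5 * (logdet_sympd(Pupd) - logdet_sympd(Ppred))
            + 0.5 * (dot(mupd, eta) - dot(mpred, Ppi * mpred))
            - g_const - 0.5 * yq(t - 1);
      if (t > 1 && abs(Pupd - PfV[t - 1]).max() <= ss_tol * trace(Pupd)) {
        ss = true;
        t_ss = t;
        Ppred_c = Ppred;
        Ppi_c = Ppi;
        Pupd_c = Pupd;
        ld_diff_c = logdet_sympd(Pupd) - logdet_sympd(Ppred);
      }
    } else {
      vec eta = Ppi_c * mpred + b;
      vec mupd = Pupd_c * eta;
      mf.col(t) = mupd;
      logZ += 0.5 * ld_diff_c
            + 0.5 * (dot(mupd, eta) - dot(mpred, Ppi_c * mpred))
            - g_const - 0.5 * yq(t - 1);
    }
  }

  if (!smooth) {
    cube Pf(d, d, T + 1);
    for (uword t = 0; t <= T; ++t) Pf.slice(t) = Pf_at(t);
    return Rcpp::List::create(
      Rcpp::Named("filtered_means") = mf.t(),
      Rcpp::Named("filtered_covs") = Pf,
      Rcpp::Named("logZ") = logZ);
  }

  // RTS backward pass with lag-one covariances Cov(x_t, x_{t-1} | y);
  // sufficient statistics are accumulated on the fly.
  mat ms(d, T + 1);
  ms.col(T) = mf.col(T);

  cube PsC, lag1C;
  if (want_moments) {
    PsC.set_size(d, d, T + 1);
    lag1C.set_size(d, d, T);
  }

  mat covsum11(d, d, fill::zeros), covsum00(d, d, fill::zeros),
      lagsum(d, d, fill::zeros);
  mat Ps_next = Pf_at(T);           // Ps(T)
  mat Ps0;                          // Ps(0), for Sinit
  if (want_moments) PsC.slice(T) = Ps_next;
  covsum11 += Ps_next;

  mat J_c; bool havJ = false;
  mat Ps_c, lag1_c; bool ssb = false;

  for (uword t = T; t >= 1; --t) {
    bool t_in_ss = ss && (t - 1 >= t_ss);  // Pf[t-1], Pp[t] both frozen
    mat J;
    if (t_in_ss && havJ) {
      J = J_c;
    } else {
      J = Pf_at(t - 1) * A.t() * inv_sympd(Pp_at(t));
      if (t_in_ss) { J_c = J; havJ = true; }
    }
    ms.col(t - 1) = mf.col(t - 1) + J * (ms.col(t) - mp.col(t));

    mat Ps_cur, lag1_cur;
    if (ssb && t_in_ss) {
      Ps_cur = Ps_c;
      lag1_cur = lag1_c;
    } else {
      Ps_cur = symm(Pf_at(t - 1) + J * (Ps_next - Pp_at(t)) * J.t());
      lag1_cur = Ps_next * J.t();
      if (t_in_ss && abs(Ps_cur - Ps_next).max() <= ss_tol * trace(Ps_cur)) {
        ssb = true;
        Ps_c = Ps_cur;
        lag1_c = lag1_cur;
      }
    }
    if (want_moments) {
      PsC.slice(t - 1) = Ps_cur;
      lag1C.slice(t - 1) = lag1_cur;
    }
    if (t - 1 >= 1) { covsum11 += Ps_cur; }
    covsum00 += Ps_cur;
    lagsum += lag1_cur;
    if (t == 1) Ps0 = Ps_cur;
    Ps_next = Ps_cur;
  }

  mat Ms1 = ms.cols(1, T), Ms0 = ms.cols(0, T - 1);
  mat S11 = Ms1 * Ms1.t() + covsum11;
  mat S00 = Ms0 * Ms0.t() + covsum00;
  mat S10 = Ms1 * Ms0.t() + lagsum;
  mat Sxy = Ms1 * y;
  mat Sinit = Ps0 + ms.col(0) * ms.col(0).t();

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("means") = ms.t(),             // (T+1) x d, row 1 is x_0
    Rcpp::Named("t_steady") = (ss ? (double)t_ss : NA_REAL),
    Rcpp::Named("logZ") = logZ,
    Rcpp::Named("S11") = symm(S11),
    Rcpp::Named("S00") = symm(S00),
    Rcpp::Named("S10") = S10,
    Rcpp::Named("Sxy") = Sxy,
    Rcpp::Named("Sinit") = symm(Sinit));
  if (want_moments) {
    out["covs"] = PsC;                         // d x d x (T+1)
    out["lag1"] = lag1C;                       // d x d x T, slice t = (t, t-1)
    cube Pf(d, d, T + 1);
    for (uword t = 0; t <= T; ++t) Pf.slice(t) = Pf_at(t);
    out["filtered_means"] = mf.t();
    out["filtered_covs"] = Pf;
  }
  return out;
}
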
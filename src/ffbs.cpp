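// Forward-filtering backward-sampling for the stacked-site dynamic linear
// model.  State x_t = vec(delta_t) of dimension n*M (factor-major), with
// diagonal evolution matrix G = diag(g), evolution covariance W (spatially
// correlated innovations), initial prior N(m0, C0) at t = 0 (no
// observation), and observation y_t = mu_t + H x_t + e_t with diagonal
// observation variance and arbitrary per-time missingness (NaN cells).
//
// Returns an exact posterior draw of the state path x_{0:T}, the
// observation log-likelihood from the prediction decomposition, and
// optionally the Rauch-Tung-Striebel smoother means and marginal
// covariances (used by the brute-force oracle comparisons).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::vec rnorm_vec(int n) {
  NumericVector z = Rcpp::rnorm(n);
  return arma::vec(z.begin(), n, true);
}

static arma::mat sympd_jitter(const arma::mat& S) {
  arma::mat A = arma::symmatu(S);
  double scale = arma::mean(A.diag());
  if (!(scale > 0)) scale = 1.0;
  double jit = 1e-10 * scale;
  arma::mat L;
  for (int k = 0; k < 8; ++k) {
    if (arma::chol(L, A + jit * arma::eye(A.n_rows, A.n_cols), "lower"))
      return A + jit * arma::eye(A.n_rows, A.n_cols);
    jit *= 100.0;
  }
  Rcpp::stop("state covariance lost positive definiteness");
}

// [[Rcpp::export(name = ".ffbs_cpp")]]
List ffbs_cpp(const arma::mat& Y,       // T x r (NaN = missing)
              const arma::mat& H,      // r x d
              const arma::mat& Mu,     // T x r (observation means)
              const arma::vec& obsvar, // r
              const arma::vec& g,      // d (diagonal of G)
              const arma::mat& W,      // d x d
              const arma::vec& m0,     // d
              const arma::mat& C0,     // d x d
              const bool do_sample,
              const bool do_moments) {
  const int T = Y.n_rows;
  const int d = H.n_cols;

  arma::mat m(d, T + 1);            // filtered means, col t = time t
  arma::cube C(d, d, T + 1);        // filtered covariances
  arma::mat a(d, T);                // predicted means (time 1..T)
  arma::cube R(d, d, T);            // predicted covariances
  double loglik = 0.0;

  m.col(0) = m0;
  C.slice(0) = sympd_jitter(C0);

  for (int t = 0; t < T; ++t) {
    arma::vec at = g % m.col(t);
    arma::mat Rt = C.slice(t);
    Rt.each_col() %= g;
    Rt.each_row() %= g.t();
    Rt = sympd_jitter(Rt + W);
    a.col(t) = at;
    R.slice(t) = Rt;

    arma::uvec obs = arma::find_finite(Y.row(t).t());
    if (obs.n_elem == 0) {
      m.col(t + 1) = at;
      C.slice(t + 1) = Rt;
      continue;
    }
    arma::mat F = H.rows(obs);
    arma::vec yt = Y.row(t).t();
    arma::vec mut = Mu.row(t).t();
    arma::vec v = yt.elem(obs) - mut.elem(obs) - F * at;
    arma::mat S = F * Rt * F.t();
    S.diag() += obsvar.elem(obs);
    S = arma::symmatu(S);
    arma::mat Ls;
    if (!arma::chol(Ls, S, "lower")) {
      S.diag() += 1e-8 * arma::mean(S.diag());
      if (!arma::chol(Ls, S, "lower"))
        Rcpp::stop("innovation covariance not positive definite");
    }
    arma::vec alpha = arma::solve(arma::trimatl(Ls), v);
    loglik += -0.5 * (obs.n_elem * std::log(2.0 * M_PI)) -
      arma::accu(arma::log(Ls.diag())) - 0.5 * arma::dot(alpha, alpha);
    arma::mat RF = Rt * F.t();                       // d x r_t
    arma::mat Kt = arma::solve(arma::trimatl(Ls), RF.t());  // r_t x d
    // m = a + RF S^{-1} v ; C = R - RF S^{-1} RF'
    m.col(t + 1) = at + Kt.t() * alpha;
    C.slice(t + 1) = arma::symmatu(Rt - Kt.t() * Kt);
  }

  List out;
  out["loglik"] = loglik;

  if (do_sample) {
    arma::mat x(d, T + 1);
    arma::mat Ct = sympd_jitter(C.slice(T));
    arma::mat L = arma::chol(Ct, "lower");
    x.col(T) = m.col(T) + L * rnorm_vec(d);
    for (int t = T - 1; t >= 0; --t) {
      // condition x_t on x_{t+1}: J = C_t G' R_{t+1}^{-1}
      arma::mat Rt = R.slice(t);
      arma::mat CG = C.slice(t);
      CG.each_row() %= g.t();                        // C_t * diag(g)
      arma::mat J = arma::solve(sympd_jitter(Rt), CG.t(),
                                arma::solve_opts::likely_sympd).t();
      arma::vec mean = m.col(t) + J * (x.col(t + 1) - a.col(t));
      arma::mat cov = sympd_jitter(C.slice(t) - J * Rt * J.t());
      arma::mat Lc = arma::chol(cov, "lower");
      x.col(t) = mean + Lc * rnorm_vec(d);
    }
    out["draw"] = x.t();                             // (T+1) x d
  }

  if (do_moments) {
    arma::mat s(d, T + 1);
    arma::cube Sm(d, d, T + 1);
    s.col(T) = m.col(T);
    Sm.slice(T) = C.slice(T);
    for (int t = T - 1; t >= 0; --t) {
      arma::mat Rt = R.slice(t);
      arma::mat CG = C.slice(t);
      CG.each_row() %= g.t();
      arma::mat J = arma::solve(sympd_jitter(Rt), CG.t(),
                                arma::solve_opts::likely_sympd).t();
      s.col(t) = m.col(t) + J * (s.col(t + 1) - a.col(t));
      Sm.slice(t) = arma::symmatu(C.slice(t) +
        J * (Sm.slice(t + 1) - Rt) * J.t());
    }
    out["smooth_mean"] = s.t();
    out["smooth_cov"] = Sm;
    out["filter_mean"] = m.t();
  }
  return out;
}
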
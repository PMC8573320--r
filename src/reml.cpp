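// Profiled restricted-likelihood kernel for the tree-level mixed model.
//
// Marginal covariance for tree i (relative to the residual variance
// sigma^2):
//   Lambda_i = Z_i diag(sd_re^2) Z_i' + w_i^2 R_i(phi),
// with R_i(phi)[j,k] = phi^|t_j - t_k| (continuous-lag AR1 over calendar
// years, so gaps from dropped years only widen the lag) and w_i a
// per-tree relative residual SD (tree 1 fixed at 1). Fixed effects and
// sigma^2 are profiled out, so the optimizer only sees theta =
//   [log sd_re (q)] [atanh(phi) (if AR1)] [log w_2..w_m (if weights)].
//
// The AR1 structure makes R_i's inverse tridiagonal (Markov process), so
// all quadratic forms are O(n) per tree; the low-rank random-effect part
// is folded in with the Woodbury identity on a q x q system.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// [[Rcpp::export]]
Rcpp::List reml_core(const arma::vec& theta,
                     const Rcpp::List& y_list,
                     const Rcpp::List& X_list,
                     const Rcpp::List& Z_list,
                     const Rcpp::List& t_list,
                     const int q,
                     const bool use_ar1,
                     const bool use_weights,
                     const bool full) {
  const int m = y_list.size();
  int idx = 0;

  vec sd_re;
  if (q > 0) {
    sd_re.set_size(q);
    for (int k = 0; k < q; ++k) sd_re[k] = std::exp(theta[idx++]);
  }
  double phi = 0.0;
  if (use_ar1) phi = std::tanh(theta[idx++]);
  vec w(m, fill::ones);
  if (use_weights) {
    for (int i = 1; i < m; ++i) w[i] = std::exp(theta[idx++]);
  }

  const mat X0 = Rcpp::as<mat>(X_list[0]);
  const int p = X0.n_cols;

  int N = 0;
  double logdet_lambda = 0.0, yPy = 0.0;
  mat A(p, p, fill::zeros);
  vec bvec(p, fill::zeros);

  const double bad = 1e10;
  Rcpp::List fail = Rcpp::List::create(Rcpp::Named("ok") = false,
                                       Rcpp::Named("deviance") = bad);

  const double log_d_sum = (q > 0) ? 2.0 * accu(log(sd_re)) : 0.0;
  vec dinv;
  if (q > 0) dinv = 1.0 / square(sd_re);

  for (int i = 0; i < m; ++i) {
    const vec y = Rcpp::as<vec>(y_list[i]);
    const mat X = Rcpp::as<mat>(X_list[i]);
    const vec t = Rcpp::as<vec>(t_list[i]);
    const int n = y.n_elem;
    N += n;
    const double w2 = w[i] * w[i];

    // M = [X | y | Z], G = M' R^{-1} M via the tridiagonal AR1 precision
    const int pc = p + 1 + q;
    mat M(n, pc);
    M.cols(0, p - 1) = X;
    M.col(p) = y;
    if (q > 0) M.cols(p + 1, pc - 1) = Rcpp::as<mat>(Z_list[i]);

    double logdet_R = 0.0;
    mat QM(n, pc);
    if (n == 1) {
      QM = M;
    } else {
      vec rho(n), a(n), b(n);   // rho[j]: corr between obs j-1 and j
      for (int j = 1; j < n; ++j) {
        const double d = std::fabs(t[j] - t[j - 1]);
        double r;
        if (phi == 0.0) {
          r = 0.0;
        } else if (phi > 0.0) {
          r = std::exp(d * std::log(phi));
        } else {
          const long long di = (long long)std::llround(d);
          if (std::fabs(d - (double)di) > 1e-9) return fail;
          r = std::exp(d * std::log(-phi));
          if (di % 2LL != 0LL) r = -r;
        }
        if (std::fabs(r) >= 1.0) return fail;   // duplicate time points
        rho[j] = r;
        const double om = 1.0 - r * r;
        a[j] = r / om;                          // -offdiag of precision
        b[j] = r * r / om;                      // diagonal increment
        logdet_R += std::log(om);
      }
      for (int j = 0; j < n; ++j) {
        double diag = 1.0;
        if (j > 0) diag += b[j];
        if (j < n - 1) diag += b[j + 1];
        QM.row(j) = diag * M.row(j);
        if (j > 0) QM.row(j) -= a[j] * M.row(j - 1);
        if (j < n - 1) QM.row(j) -= a[j + 1] * M.row(j + 1);
      }
    }
    mat G = M.t() * QM;           // (p+1+q)^2, symmetric

    mat Gxx = G.submat(0, 0, p - 1, p - 1);
    vec Gxy = G.submat(0, p, p - 1, p);
    double Gyy = G(p, p);
    double block_logdet = (double)n * std::log(w2) + logdet_R;

    if (q > 0) {
      mat Gxz = G.submat(0, p + 1, p - 1, pc - 1);
      rowvec Gyz = G.submat(p, p + 1, p, pc - 1);
      mat Gzz = G.submat(p + 1, p + 1, pc - 1, pc - 1);
      mat C = w2 * diagmat(dinv) + 0.5 * (Gzz + Gzz.t());  // Woodbury core
      mat Cc;
      if (!chol(Cc, C, "lower")) return fail;
      mat CiGzx = solve(trimatu(Cc.t()),
                        solve(trimatl(Cc), Gxz.t()));
      vec CiGzy = solve(trimatu(Cc.t()),
                        solve(trimatl(Cc), Gyz.t()));
      Gxx -= Gxz * CiGzx;
      Gxy -= Gxz * CiGzy;
      Gyy -= dot(Gyz, CiGzy);
      block_logdet += log_d_sum + 2.0 * accu(log(Cc.diag())) -
        (double)q * std::log(w2);
    }
    A += Gxx / w2;
    bvec += Gxy / w2;
    yPy += Gyy / w2;
    logdet_lambda += block_logdet;
  }

  A = 0.5 * (A + A.t());          // exact symmetry despite rounding
  mat Ainv;
  if (!inv_sympd(Ainv, A)) return fail;
  const vec beta = Ainv * bvec;
  const double rss = yPy - dot(bvec, beta);
  if (!(rss > 0.0) || !std::isfinite(rss)) return fail;
  const double df = (double)(N - p);
  const double sigma2 = rss / df;

  double ldA, sgn;
  log_det(ldA, sgn, A);
  if (sgn <= 0.0) return fail;
  const double loglik = -0.5 * (df * std::log(2.0 * M_PI) +
                                df * std::log(sigma2) + df +
                                logdet_lambda + ldA);

  if (!full) {
    return Rcpp::List::create(Rcpp::Named("ok") = true,
                              Rcpp::Named("deviance") = -2.0 * loglik);
  }
  return Rcpp::List::create(
      Rcpp::Named("ok") = true,
      Rcpp::Named("deviance") = -2.0 * loglik,
      Rcpp::Named("loglik") = loglik,
      Rcpp::Named("beta") = beta,
      Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("vcov_beta") = sigma2 * Ainv,
      Rcpp::Named("sd_re") = sd_re,
      Rcpp::Named("phi") = phi,
      Rcpp::Named("weights") = w,
      Rcpp::Named("n_obs") = N);
}
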
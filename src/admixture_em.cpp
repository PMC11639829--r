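// EM for the binomial admixture model.
//
// d_im ~ Binomial(2, p_im), p_im = sum_k Q_ik F_km. Missing dosages are
// encoded as a negative value and excluded from every sum. The multiplicative
// EM updates are
//   a_imk = Q_ik F_km / p_im            (expected alt-allele copies)
//   b_imk = Q_ik (1 - F_km) / (1 - p_im) (expected ref-allele copies)
//   F_km <- sum_i d a / (sum_i d a + (2-d) b)
//   Q_ik <- sum_m (d a + (2-d) b) / (2 * M_i)
// which never leave the simplex and increase the likelihood monotonically.
// The E and M steps are fused into one cache-friendly pass per iteration;
// the log-likelihood of the pre-update parameters falls out of the same
// pass for free, so each trace entry t is ll(theta_t) and one closing pass
// scores the final parameters.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double P_LO = 1e-9, P_HI = 1.0 - 1e-9;
static const double F_LO = 1e-6, F_HI = 1.0 - 1e-6;

// log-likelihood only (no update); D column-major N x M, missing < 0
static double loglik_pass(const mat& D, const mat& Q, const mat& F) {
  const uword N = D.n_rows, M = D.n_cols, K = Q.n_cols;
  const double* d = D.memptr();
  const double* q = Q.memptr();
  const double* f = F.memptr();
  double ll = 0.0;
  for (uword m = 0; m < M; ++m) {
    const double* fm = f + m * K;
    for (uword i = 0; i < N; ++i) {
      double dim = d[i + m * N];
      if (dim < 0) continue;
      double p = 0.0;
      for (uword k = 0; k < K; ++k) p += q[i + k * N] * fm[k];
      p = std::min(std::max(p, P_LO), P_HI);
      ll += dim * std::log(p) + (2.0 - dim) * std::log1p(-p);
    }
  }
  return ll;
}

// [[Rcpp::export]]
Rcpp::List admixture_em_cpp(const arma::mat& D, const arma::mat& Q0,
                            const arma::mat& F0, double tol, int max_iter) {
  const uword N = D.n_rows, M = D.n_cols, K = Q0.n_cols;
  mat Q = Q0;
  mat F = clamp(F0, F_LO, F_HI);

  vec Mi(N, fill::zeros);  // non-missing variants per sample
  for (uword m = 0; m < M; ++m)
    for (uword i = 0; i < N; ++i)
      if (D(i, m) >= 0) Mi(i) += 1.0;
  Mi.replace(0.0, 1.0);

  std::vector<double> trace;
  trace.reserve(max_iter + 1);
  bool converged = false;

  mat Qacc(N, K), Falt(K, M), Ftot(K, M);
  std::vector<double> a(K), b(K);
  for (int it = 0; it < max_iter; ++it) {
    Qacc.zeros(); Falt.zeros(); Ftot.zeros();
    double ll = 0.0;  // of the current (pre-update) parameters
    const double* dptr = D.memptr();
    const double* qptr = Q.memptr();
    const double* fptr = F.memptr();
    double* qa = Qacc.memptr();
    double* fa = Falt.memptr();
    double* ft = Ftot.memptr();
    for (uword m = 0; m < M; ++m) {
      const double* fm = fptr + m * K;
      double* fam = fa + m * K;
      double* ftm = ft + m * K;
      for (uword i = 0; i < N; ++i) {
        double dim = dptr[i + m * N];
        if (dim < 0) continue;
        double p = 0.0;
        for (uword k = 0; k < K; ++k) p += qptr[i + k * N] * fm[k];
        p = std::min(std::max(p, P_LO), P_HI);
        ll += dim * std::log(p) + (2.0 - dim) * std::log1p(-p);
        double ralt = dim / p, rref = (2.0 - dim) / (1.0 - p);
        for (uword k = 0; k < K; ++k) {
          double qik = qptr[i + k * N];
          double ak = qik * fm[k] * ralt;
          double bk = qik * (1.0 - fm[k]) * rref;
          fam[k] += ak;
          ftm[k] += ak + bk;
          qa[i + k * N] += ak + bk;
        }
      }
    }
    if (!std::isfinite(ll))
      Rcpp::stop("non-finite log-likelihood at iteration %d", it + 1);
    trace.push_back(ll);

    Ftot.replace(0.0, 1.0);
    F = clamp(Falt / Ftot, F_LO, F_HI);
    Qacc.each_col() /= (2.0 * Mi);
    vec rs = sum(Qacc, 1);      // renormalise against numerical drift
    rs.replace(0.0, 1.0);
    Qacc.each_col() /= rs;
    Q = Qacc;

    if (it > 0) {
      double prev = trace[it - 1];
      double rel = std::fabs(ll - prev) / (std::fabs(prev) + 1e-12);
      if (rel < tol) { converged = true; break; }
    }
  }
  trace.push_back(loglik_pass(D, Q, F));  // final parameters

  return Rcpp::List::create(
      Rcpp::Named("Q") = Q, Rcpp::Named("F") = F,
      Rcpp::Named("loglik_trace") = trace,
      Rcpp::Named("converged") = converged);
}

// [[Rcpp::export]]
double admixture_loglik_cpp(const arma::mat& D, const arma::mat& Q,
                            const arma::mat& F) {
  return loglik_pass(D, Q, F);
}
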
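// Hot loops of the Gibbs sampler. The component marginal covariance
// Z_i D_k Z_i' + Phi_i is never formed: with M = D_k^{-1} + Z_i' Phi^{-1} Z_i
// the matrix determinant lemma gives
//   log|Sigma| = sum log phi + log|D_k| + log|M|
// and Woodbury gives the quadratic form from the q-dimensional statistics
//   u0_i = Z_i' Phi^{-1} (y_i - X_i beta),  A_i = Z_i' Phi^{-1} Z_i,
//   rq0_i = (y_i - X_i beta)' Phi^{-1} (y_i - X_i beta),
// which subject_stats_cpp accumulates once per sweep. All randomness comes
// from R's RNG so chains are bit-reproducible under set.seed().
#include <RcppArmadillo.h>
using namespace Rcpp;

// Per-subject sufficient statistics at the current (beta, phi).
// obs_region is 0-based; tt is time on the slope scale (months/time_scale).
// [[Rcpp::export]]
List subject_stats_cpp(const arma::vec& y,
                       const IntegerVector& sub_start,
                       const IntegerVector& sub_len,
                       const IntegerVector& obs_region,
                       const arma::vec& tt,
                       const arma::vec& fixpart,
                       const arma::vec& phi) {
  const int N = sub_start.size();
  const int J = phi.n_elem;
  const int q = 2 * J;
  arma::mat u0(q, N, arma::fill::zeros);
  arma::cube A(q, q, N, arma::fill::zeros);
  arma::vec rq0(N, arma::fill::zeros);
  arma::vec nlogphi(N, arma::fill::zeros);
  for (int i = 0; i < N; ++i) {
    const int s = sub_start[i];
    const int n = sub_len[i];
    for (int l = s; l < s + n; ++l) {
      const int j = obs_region[l];
      const double ip = 1.0 / phi[j];
      const double t = tt[l];
      const double e = y[l] - fixpart[l];
      u0(2 * j, i) += e * ip;
      u0(2 * j + 1, i) += e * t * ip;
      A(2 * j, 2 * j, i) += ip;
      A(2 * j, 2 * j + 1, i) += t * ip;
      A(2 * j + 1, 2 * j, i) += t * ip;
      A(2 * j + 1, 2 * j + 1, i) += t * t * ip;
      rq0[i] += e * e * ip;
      nlogphi[i] += std::log(phi[j]);
    }
  }
  return List::create(_["u0"] = u0, _["A"] = A, _["rq0"] = rq0,
                      _["nlogphi"] = nlogphi);
}

// In-place lower Cholesky of a small symmetric PD matrix (q is 2J, so
// typically <= 16: a hand-rolled factor beats the LAPACK call overhead).
static inline bool chol_lower(double* L, const int n) {
  for (int j = 0; j < n; ++j) {
    double d = L[j + j * n];
    for (int t = 0; t < j; ++t) d -= L[j + t * n] * L[j + t * n];
    if (d <= 0.0 || !std::isfinite(d)) return false;
    d = std::sqrt(d);
    L[j + j * n] = d;
    for (int i = j + 1; i < n; ++i) {
      double s = L[i + j * n];
      for (int t = 0; t < j; ++t) s -= L[i + t * n] * L[j + t * n];
      L[i + j * n] = s / d;
    }
  }
  return true;
}

static inline void forward_solve(const double* L, double* v, const int n) {
  for (int i = 0; i < n; ++i) {
    double s = v[i];
    for (int t = 0; t < i; ++t) s -= L[i + t * n] * v[t];
    v[i] = s / L[i + i * n];
  }
}

static inline void backward_solve_t(const double* L, double* v, const int n) {
  for (int i = n - 1; i >= 0; --i) {
    double s = v[i];
    for (int t = i + 1; t < n; ++t) s -= L[t + i * n] * v[t];
    v[i] = s / L[i + i * n];
  }
}

// N x K matrix of component marginal log-densities log f_{i,k}(y_i).
// logdetD holds log|D_k|; Dinv the component precisions.
// [[Rcpp::export]]
arma::mat comp_logdens_stats_cpp(const arma::mat& u0,
                                 const arma::cube& A,
                                 const arma::vec& rq0,
                                 const arma::vec& nlogphi,
                                 const IntegerVector& sub_len,
                                 const arma::mat& mu,
                                 const arma::cube& Dinv,
                                 const arma::vec& logdetD) {
  const int N = u0.n_cols;
  const int K = mu.n_cols;
  const int q = u0.n_rows;
  arma::mat out(N, K);
  const double l2pi = std::log(2.0 * M_PI);
  std::vector<double> M(q * q), v(q), Amu(q);
  for (int i = 0; i < N; ++i) {
    const double* Ai = A.slice(i).memptr();
    const double* u0i = u0.colptr(i);
    for (int k = 0; k < K; ++k) {
      const double* mk = mu.colptr(k);
      const double* Dk = Dinv.slice(k).memptr();
      double mu_u0 = 0.0, mu_Amu = 0.0;
      for (int a = 0; a < q; ++a) {
        double s = 0.0;
        for (int bcol = 0; bcol < q; ++bcol) s += Ai[a + bcol * q] * mk[bcol];
        Amu[a] = s;
        mu_u0 += mk[a] * u0i[a];
        mu_Amu += mk[a] * s;
        v[a] = u0i[a] - s;
        for (int bcol = 0; bcol < q; ++bcol)
          M[a + bcol * q] = Dk[a + bcol * q] + Ai[a + bcol * q];
      }
      if (!chol_lower(M.data(), q))
        stop("marginal precision not positive definite (subject %d, component %d)",
             i + 1, k + 1);
      forward_solve(M.data(), v.data(), q);
      double vv = 0.0, logdetM = 0.0;
      for (int a = 0; a < q; ++a) {
        vv += v[a] * v[a];
        logdetM += std::log(M[a + a * q]);
      }
      const double quad = rq0[i] - 2.0 * mu_u0 + mu_Amu - vv;
      const double logdet = nlogphi[i] + logdetD[k] + 2.0 * logdetM;
      out(i, k) = -0.5 * (sub_len[i] * l2pi + logdet + quad);
    }
  }
  return out;
}

// Draws b_i | y_i, U_i=k ~ N(Q^{-1} rhs, Q^{-1}) with Q = A_i + D_k^{-1},
// rhs = u0_i + D_k^{-1} mu_k. U is 1-based. Returns N x q.
// [[Rcpp::export]]
arma::mat draw_b_stats_cpp(const arma::mat& u0,
                           const arma::cube& A,
                           const arma::mat& mu,
                           const arma::cube& Dinv,
                           const IntegerVector& U) {
  const int N = u0.n_cols;
  const int q = u0.n_rows;
  arma::mat out(N, q);
  std::vector<double> Q(q * q), m(q), z(q);
  for (int i = 0; i < N; ++i) {
    const int k = U[i] - 1;
    const double* Ai = A.slice(i).memptr();
    const double* Dk = Dinv.slice(k).memptr();
    const double* mk = mu.colptr(k);
    const double* u0i = u0.colptr(i);
    for (int a = 0; a < q; ++a) {
      double s = 0.0;
      for (int bcol = 0; bcol < q; ++bcol) {
        Q[a + bcol * q] = Dk[a + bcol * q] + Ai[a + bcol * q];
        s += Dk[a + bcol * q] * mk[bcol];
      }
      m[a] = u0i[a] + s;  // rhs
    }
    if (!chol_lower(Q.data(), q))
      stop("random-effect precision not positive definite (subject %d)", i + 1);
    forward_solve(Q.data(), m.data(), q);
    backward_solve_t(Q.data(), m.data(), q);  // m = Q^{-1} rhs
    for (int a = 0; a < q; ++a) z[a] = norm_rand();
    backward_solve_t(Q.data(), z.data(), q);  // L'^{-1} z ~ N(0, Q^{-1})
    for (int a = 0; a < q; ++a) out(i, a) = m[a] + z[a];
  }
  return out;
}
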
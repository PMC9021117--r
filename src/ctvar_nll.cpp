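// Negative log-likelihood of the continuous-time VAR (multivariate
// Ornstein-Uhlenbeck) transition model on irregularly spaced pairs.
//
// Parameter vector layout (length p^2 + p(p+1)/2):
//   - first p^2 entries: drift matrix A, column-major;
//   - remaining entries: lower-triangular Cholesky factor L of the
//     diffusion rate Q = L L', column-major by column, with log-diagonal.
//
// Each consecutive fully-observed pair (y0 -> y1, interval dt) contributes
// a Gaussian term with mean e^{A dt} y0 and covariance
// Sigma(dt) = Gamma - e^{A dt} Gamma e^{A' dt}, Gamma the stationary
// covariance. Everything is evaluated in the eigenbasis of A, so each pair
// costs O(p^3) flops on small preallocated buffers after a single
// eigendecomposition per call (intervals are typically all distinct for
// experience-sampling schedules, so nothing can be shared across pairs).
//
// Unstable or numerically degenerate parameter points return a large
// finite penalty so that quasi-Newton optimizers can step past them.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double BIG = 1e10;

// [[Rcpp::export]]
double ctvar_nll_cpp(const arma::vec& par, const arma::mat& y0,
                     const arma::mat& y1, const arma::vec& dt) {
  const uword p = y0.n_cols;
  const uword n = y0.n_rows;
  if (par.n_elem != p * p + p * (p + 1) / 2)
    Rcpp::stop("parameter vector has wrong length");
  if (y1.n_rows != n || y1.n_cols != p || dt.n_elem != n)
    Rcpp::stop("inconsistent data dimensions");

  mat A(p, p);
  uword k = 0;
  for (uword j = 0; j < p; ++j)
    for (uword i = 0; i < p; ++i) A(i, j) = par(k++);

  mat L(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j)
    for (uword i = j; i < p; ++i) {
      double v = par(k++);
      L(i, j) = (i == j) ? std::exp(v) : v;
    }
  mat Q = L * L.t();

  cx_vec lam;
  cx_mat V;
  if (!eig_gen(lam, V, A)) return BIG;
  for (uword i = 0; i < p; ++i)
    if (lam(i).real() >= -1e-8) return BIG;

  cx_mat Vinv;
  if (!inv(Vinv, V)) return BIG;

  // Stationary covariance in the eigenbasis: G = -(Vinv Q Vinv^T) ./
  // (lam_i + lam_j)   (plain transpose, not conjugate).
  cx_mat G = Vinv * cx_mat(Q, mat(p, p, fill::zeros)) * Vinv.st();
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      G(i, j) /= -(lam(i) + lam(j));

  // Data in the eigenbasis, once.
  cx_mat B0 = Vinv * cx_mat(y0.t(), mat(p, n, fill::zeros));

  const double log2pi = std::log(2.0 * M_PI);
  const std::complex<double>* Vp = V.memptr();
  const std::complex<double>* Gp = G.memptr();

  // preallocated per-pair buffers
  std::vector<std::complex<double>> e(p), w(p), T1(p * p), Gd(p * p);
  std::vector<double> S(p * p), C(p * p), resid(p), z(p);

  double nll = 0.0;
  for (uword obs = 0; obs < n; ++obs) {
    const double d = dt(obs);
    const std::complex<double>* b0 = B0.colptr(obs);
    for (uword r = 0; r < p; ++r) {
      e[r] = std::exp(lam(r) * d);
      w[r] = e[r] * b0[r];
    }
    // residual: y1 - Re(V w)
    for (uword r = 0; r < p; ++r) {
      std::complex<double> acc(0.0, 0.0);
      for (uword c = 0; c < p; ++c) acc += Vp[r + c * p] * w[c];
      resid[r] = y1(obs, r) - acc.real();
    }
    // Sigma(d) = Re( V (G .* (1 - e e^T)) V^T )
    for (uword c = 0; c < p; ++c)
      for (uword r = 0; r < p; ++r)
        Gd[r + c * p] = Gp[r + c * p] * (1.0 - e[r] * e[c]);
    for (uword c = 0; c < p; ++c)       // T1 = V * Gd
      for (uword r = 0; r < p; ++r) {
        std::complex<double> acc(0.0, 0.0);
        for (uword m = 0; m < p; ++m) acc += Vp[r + m * p] * Gd[m + c * p];
        T1[r + c * p] = acc;
      }
    for (uword c = 0; c < p; ++c)       // S = Re(T1 * V^T)
      for (uword r = 0; r <= c; ++r) {
        std::complex<double> acc(0.0, 0.0);
        for (uword m = 0; m < p; ++m) acc += T1[r + m * p] * Vp[c + m * p];
        S[r + c * p] = acc.real();
        S[c + r * p] = acc.real();
      }
    // in-place lower Cholesky of S into C
    double logdet = 0.0;
    bool ok = true;
    for (uword c = 0; c < p && ok; ++c) {
      double diag = S[c + c * p];
      for (uword m = 0; m < c; ++m) diag -= C[c + m * p] * C[c + m * p];
      if (diag <= 0.0 || !std::isfinite(diag)) { ok = false; break; }
      const double dr = std::sqrt(diag);
      C[c + c * p] = dr;
      logdet += std::log(dr);
      for (uword r = c + 1; r < p; ++r) {
        double acc = S[r + c * p];
        for (uword m = 0; m < c; ++m) acc -= C[r + m * p] * C[c + m * p];
        C[r + c * p] = acc / dr;
      }
    }
    if (!ok) return BIG;
    // z = C^{-1} resid by forward substitution
    double quad = 0.0;
    for (uword r = 0; r < p; ++r) {
      double acc = resid[r];
      for (uword m = 0; m < r; ++m) acc -= C[r + m * p] * z[m];
      z[r] = acc / C[r + r * p];
      quad += z[r] * z[r];
    }
    nll += 0.5 * (p * log2pi + quad) + logdet;
    if (!std::isfinite(nll)) return BIG;
  }
  return nll;
}
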
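// Profiled marginal log-likelihood machinery for single-grouping-factor
// linear mixed models (random intercept, or random intercept + slope).
//
// Model, per subject i:
//   y_i = X_i beta + Z_i b_i + e_i,   b_i ~ N(0, sigma2 * Lambda Lambda'),
//   e_i ~ N(0, sigma2 * I).
// Lambda is the lower-triangular relative covariance factor; beta and sigma2
// are profiled out, so the optimiser only sees the 1 (intercept-only) or 3
// (intercept+slope) free elements of Lambda.
//
// Design- and response-level sufficient statistics (Z'Z, Z'X, X'X, Z'y, X'y,
// y'y) are computed once per fit and held behind an external pointer; each
// objective evaluation is allocation-free scalar arithmetic on the 1x1 or
// 2x2 capacitance matrix S_i = I + L' Z_i'Z_i L (Woodbury identity), so a
// genome-wide scan spends its time in the optimiser, not in marshalling.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct LmmProblem {
  int n, p, m;
  cube ZtZ;   // 2 x 2 x m
  cube ZtX;   // 2 x p x m
  mat XtX;    // p x p
  mat Zty;    // 2 x m
  vec Xty;    // p
  double yty;
};

// [[Rcpp::export]]
SEXP lmm_problem_cpp(const arma::mat& X, const arma::mat& Z, const arma::vec& y,
                     const arma::ivec& starts, const arma::ivec& ends) {
  const int m = starts.n_elem;
  const int p = X.n_cols;
  LmmProblem* pr = new LmmProblem;
  pr->n = X.n_rows;
  pr->p = p;
  pr->m = m;
  pr->ZtZ.set_size(2, 2, m);
  pr->ZtX.set_size(2, p, m);
  pr->Zty.set_size(2, m);
  for (int i = 0; i < m; ++i) {
    const mat Zi = Z.rows(starts[i], ends[i]);
    const mat Xi = X.rows(starts[i], ends[i]);
    pr->ZtZ.slice(i) = Zi.t() * Zi;
    pr->ZtX.slice(i) = Zi.t() * Xi;
    pr->Zty.col(i) = Zi.t() * y.subvec(starts[i], ends[i]);
  }
  pr->XtX = X.t() * X;
  pr->Xty = X.t() * y;
  pr->yty = dot(y, y);
  return Rcpp::XPtr<LmmProblem>(pr, true);
}

// Accumulate A = X'V^{-1}X, b = X'V^{-1}y, c = y'V^{-1}y and sum log|V_i|
// for the given Lambda. q = 1 uses only the first row/col of the blocks.
static void accumulate(const LmmProblem& pr, const double* th, int q,
                       mat& A, vec& b, double& c, double& logdet) {
  const int p = pr.p;
  A = pr.XtX;
  b = pr.Xty;
  c = pr.yty;
  logdet = 0.0;
  std::vector<double> G1(p), G2(p), H1(p), H2(p);
  if (q == 1) {
    const double l = th[0];
    const double l2 = l * l;
    for (int i = 0; i < pr.m; ++i) {
      const double z11 = pr.ZtZ(0, 0, i);
      const double s = 1.0 + l2 * z11;
      logdet += std::log(s);
      const double w = l2 / s;  // L S^{-1} L'
      for (int j = 0; j < p; ++j) G1[j] = pr.ZtX(0, j, i);
      const double g1 = pr.Zty(0, i);
      for (int j = 0; j < p; ++j) {
        const double wg = w * G1[j];
        for (int k = j; k < p; ++k) A(j, k) -= wg * G1[k];
        b[j] -= wg * g1;
      }
      c -= w * g1 * g1;
    }
  } else {
    const double l11 = th[0], l21 = th[1], l22 = th[2];
    for (int i = 0; i < pr.m; ++i) {
      const double z11 = pr.ZtZ(0, 0, i), z12 = pr.ZtZ(0, 1, i), z22 = pr.ZtZ(1, 1, i);
      // B = L' Z'Z, rows of the 2 x 2 product
      const double b11 = l11 * z11 + l21 * z12, b12 = l11 * z12 + l21 * z22;
      const double b21 = l22 * z12, b22 = l22 * z22;
      // S = I + B L
      const double s11 = 1.0 + b11 * l11 + b12 * l21;
      const double s12 = b12 * l22;
      const double s22 = 1.0 + b22 * l22;
      const double det = s11 * s22 - s12 * s12;
      logdet += std::log(det);
      const double i11 = s22 / det, i12 = -s12 / det, i22 = s11 / det;
      // G = L' Z'X (2 x p), g = L' Z'y
      for (int j = 0; j < p; ++j) {
        const double a1 = pr.ZtX(0, j, i), a2 = pr.ZtX(1, j, i);
        G1[j] = l11 * a1 + l21 * a2;
        G2[j] = l22 * a2;
        H1[j] = i11 * G1[j] + i12 * G2[j];
        H2[j] = i12 * G1[j] + i22 * G2[j];
      }
      const double g1 = l11 * pr.Zty(0, i) + l21 * pr.Zty(1, i);
      const double g2 = l22 * pr.Zty(1, i);
      const double h1 = i11 * g1 + i12 * g2, h2 = i12 * g1 + i22 * g2;
      for (int j = 0; j < p; ++j) {
        for (int k = j; k < p; ++k) A(j, k) -= G1[j] * H1[k] + G2[j] * H2[k];
        b[j] -= G1[j] * h1 + G2[j] * h2;
      }
      c -= g1 * h1 + g2 * h2;
    }
  }
  A = symmatu(A);
}

static double deviance_impl(const LmmProblem& pr, const double* th, int q,
                            bool reml, mat& A, vec& b, vec& beta,
                            double& qres, double& logdet, double& sig2) {
  double c;
  accumulate(pr, th, q, A, b, c, logdet);
  if (!solve(beta, A, b, solve_opts::likely_sympd)) return 1e10;
  qres = c - dot(b, beta);
  if (!std::isfinite(qres)) return 1e10;
  if (qres < 1e-12) qres = 1e-12;
  const double twopi = 2.0 * M_PI;
  if (!reml) {
    sig2 = qres / pr.n;
    return pr.n * std::log(twopi * sig2) + logdet + qres / sig2;
  }
  double ldA, signA;
  log_det(ldA, signA, A);
  sig2 = qres / (pr.n - pr.p);
  return (pr.n - pr.p) * std::log(twopi * sig2) + logdet + ldA + qres / sig2;
}

// [[Rcpp::export]]
double lmm_deviance_cpp(const arma::vec& theta, SEXP prob, bool reml) {
  Rcpp::XPtr<LmmProblem> pr(prob);
  const int q = theta.n_elem == 1 ? 1 : 2;
  mat A;
  vec b, beta;
  double qres, logdet, sig2;
  return deviance_impl(*pr, theta.memptr(), q, reml, A, b, beta, qres, logdet, sig2);
}

// [[Rcpp::export]]
Rcpp::List lmm_details_cpp(const arma::vec& theta, SEXP prob, bool reml) {
  Rcpp::XPtr<LmmProblem> pr(prob);
  const int q = theta.n_elem == 1 ? 1 : 2;
  mat A;
  vec b, beta;
  double qres, logdet, sig2;
  const double dev =
      deviance_impl(*pr, theta.memptr(), q, reml, A, b, beta, qres, logdet, sig2);
  const mat Ainv = inv_sympd(A);
  // Lambda and Psi
  mat L(q, q, fill::zeros);
  L(0, 0) = theta[0];
  if (q == 2) {
    L(1, 0) = theta[1];
    L(1, 1) = theta[2];
  }
  // BLUPs: b_i = L S_i^{-1} L' (Z_i'y_i - Z_i'X_i beta)
  mat blups(pr->m, q);
  const mat Iq = eye(q, q);
  for (int i = 0; i < pr->m; ++i) {
    const mat zz = pr->ZtZ.slice(i).submat(0, 0, q - 1, q - 1);
    const mat S = Iq + L.t() * zz * L;
    const vec t = pr->Zty.col(i).subvec(0, q - 1) -
                  pr->ZtX.slice(i).rows(0, q - 1) * beta;
    blups.row(i) = (L * solve(symmatu(S), L.t() * t)).t();
  }
  return Rcpp::List::create(
      Rcpp::Named("beta") = beta,
      Rcpp::Named("vcov") = sig2 * Ainv,
      Rcpp::Named("sigma2") = sig2,
      Rcpp::Named("Psi") = sig2 * (L * L.t()),
      Rcpp::Named("loglik") = -0.5 * dev,
      Rcpp::Named("blups") = blups,
      Rcpp::Named("qres") = qres);
}
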
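// Profiled deviance for a two-level linear mixed model with person-level
// random effects  b_j ~ N(0, sigma^2 * Lambda Lambda'), residuals N(0, sigma^2).
//
// All data-dependent cross-products (X'X, X'y, y'y and the per-person
// Z_j'X_j, Z_j'Z_j, Z_j'y_j) are computed once and cached behind an external
// pointer; each deviance evaluation then only does O(J q^2 p) work via the
// Woodbury identity  W_j = I - A_j M_j^{-1} A_j',  A_j = Z_j Lambda,
// M_j = I_q + Lambda' Z_j'Z_j Lambda. Fixed effects and sigma^2 are profiled
// out, leaving an optimization over the relative Cholesky factor Lambda.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

struct LmmData {
  cube G;        // q x p x J : Z_j' X_j
  cube H;        // q x q x J : Z_j' Z_j
  mat g;         // q x J     : Z_j' y_j
  mat XtX;       // p x p
  vec Xty;       // p
  double yty;
  int n, p, q, J;
  mat SW;        // (J q) x p workspace: whitened per-person blocks
  vec sw;        // (J q) workspace
};

static mat lambda_from_theta(const vec& theta, int q) {
  mat L(q, q, fill::zeros);
  int k = 0;
  for (int j = 0; j < q; ++j)
    for (int i = j; i < q; ++i)
      L(i, j) = theta(k++);
  return L;
}

// [[Rcpp::export(name = ".lmm_precompute_cpp")]]
SEXP lmm_precompute_cpp(const arma::vec& y,
                        const arma::mat& X,
                        const arma::mat& Z,
                        const arma::ivec& grp_start,
                        const arma::ivec& grp_len) {
  if (Z.n_cols > 3)
    Rcpp::stop("at most 3 random-effect columns are supported");
  LmmData* d = new LmmData();
  d->n = y.n_elem;
  d->p = X.n_cols;
  d->q = Z.n_cols;
  d->J = grp_start.n_elem;
  d->G.set_size(d->q, d->p, d->J);
  d->H.set_size(d->q, d->q, d->J);
  d->g.set_size(d->q, d->J);
  d->XtX = X.t() * X;
  d->Xty = X.t() * y;
  d->yty = dot(y, y);
  for (int j = 0; j < d->J; ++j) {
    const int s = grp_start(j);
    const int e = s + grp_len(j) - 1;
    const mat Xj = X.rows(s, e);
    const mat Zj = Z.rows(s, e);
    const vec yj = y.subvec(s, e);
    d->G.slice(j) = Zj.t() * Xj;
    d->H.slice(j) = Zj.t() * Zj;
    d->g.col(j) = Zj.t() * yj;
  }
  d->SW.set_size(d->J * d->q, d->p);
  d->sw.set_size(d->J * d->q);
  Rcpp::XPtr<LmmData> ptr(d, true);
  return ptr;
}

static Rcpp::List profile_impl(LmmData* d, const mat& L, bool reml) {
  const int p = d->p, q = d->q, J = d->J, n = d->n;
  double logdet = 0.0;

  // allocation-free per-person pass: M_j = I + L'H_jL, Cholesky, and the
  // whitened blocks Mchol^{-1} L'G_j written into one stacked workspace so
  // the p x p accumulation happens in a single syrk at the end
  double M[9], C[9], B[3], tmp[9];
  for (int j = 0; j < J; ++j) {
    const double* Hj = d->H.slice(j).memptr();
    // tmp = H_j L ; M = I + L' tmp
    for (int c = 0; c < q; ++c)
      for (int r = 0; r < q; ++r) {
        double acc = 0.0;
        for (int k = 0; k < q; ++k) acc += Hj[r + k * q] * L(k, c);
        tmp[r + c * q] = acc;
      }
    for (int c = 0; c < q; ++c)
      for (int r = 0; r < q; ++r) {
        double acc = (r == c) ? 1.0 : 0.0;
        for (int k = 0; k < q; ++k) acc += L(k, r) * tmp[k + c * q];
        M[r + c * q] = acc;
      }
    // in-place lower Cholesky of M into C
    for (int c = 0; c < q; ++c) {
      for (int r = c; r < q; ++r) {
        double acc = M[r + c * q];
        for (int k = 0; k < c; ++k) acc -= C[r + k * q] * C[c + k * q];
        if (r == c) {
          if (acc <= 0.0)
            return Rcpp::List::create(Rcpp::Named("deviance") = R_PosInf,
                                      Rcpp::Named("singular") = true);
          C[c + c * q] = std::sqrt(acc);
        } else {
          C[r + c * q] = acc / C[c + c * q];
        }
      }
      logdet += 2.0 * std::log(C[c + c * q]);
    }
    // whiten G block: rows j*q..j*q+q-1 of SW <- C^{-1} (L' G_j)
    const double* Gj = d->G.slice(j).memptr();   // q x p
    double* SWj = d->SW.memptr();                // (Jq) x p, column-major
    const arma::uword ldSW = d->SW.n_rows;
    for (int c = 0; c < p; ++c) {
      for (int r = 0; r < q; ++r) {
        double acc = 0.0;
        for (int k = 0; k < q; ++k) acc += L(k, r) * Gj[k + c * q];
        B[r] = acc;
      }
      for (int r = 0; r < q; ++r) {            // forward substitution
        double acc = B[r];
        for (int k = 0; k < r; ++k) acc -= C[r + k * q] * B[k];
        B[r] = acc / C[r + r * q];
      }
      for (int r = 0; r < q; ++r)
        SWj[(arma::uword)(j * q + r) + (arma::uword)c * ldSW] = B[r];
    }
    // whiten g vector
    const double* gj = d->g.colptr(j);
    for (int r = 0; r < q; ++r) {
      double acc = 0.0;
      for (int k = 0; k < q; ++k) acc += L(k, r) * gj[k];
      B[r] = acc;
    }
    for (int r = 0; r < q; ++r) {
      double acc = B[r];
      for (int k = 0; k < r; ++k) acc -= C[r + k * q] * B[k];
      B[r] = acc / C[r + r * q];
    }
    for (int r = 0; r < q; ++r) d->sw((arma::uword)(j * q + r)) = B[r];
  }

  mat XtWX = d->XtX - d->SW.t() * d->SW;
  vec XtWy = d->Xty - d->SW.t() * d->sw;
  double ytWy = d->yty - dot(d->sw, d->sw);

  vec beta;
  bool ok = solve(beta, XtWX, XtWy, solve_opts::no_approx);
  if (!ok)
    return Rcpp::List::create(Rcpp::Named("deviance") = R_PosInf,
                              Rcpp::Named("singular") = true);
  double rss = ytWy - dot(beta, XtWy);
  if (rss < 1e-300) rss = 1e-300;

  const double df = reml ? (double)(n - p) : (double)n;
  double sigma2 = rss / df;
  double dev = df * std::log(2.0 * M_PI * sigma2) + logdet + df;
  if (reml) {
    double ldX, sign;
    log_det(ldX, sign, XtWX);
    dev += ldX;
  }
  return Rcpp::List::create(
      Rcpp::Named("deviance") = dev,
      Rcpp::Named("beta") = beta,
      Rcpp::Named("sigma2") = sigma2,
      Rcpp::Named("rss") = rss,
      Rcpp::Named("logdet") = logdet,
      Rcpp::Named("XtWX") = XtWX,
      Rcpp::Named("singular") = false);
}

// [[Rcpp::export(name = ".lmm_profile_cpp")]]
Rcpp::List lmm_profile_cpp(SEXP xp, const arma::vec& theta, const bool reml) {
  Rcpp::XPtr<LmmData> d(xp);
  mat L = lambda_from_theta(theta, d->q);
  return profile_impl(d, L, reml);
}

// Minus twice the log-likelihood at explicit variance parameters (Sigma,
// sigma^2_e), fixed effects profiled out; used for observed-information
// standard errors of the variance components.
// [[Rcpp::export(name = ".lmm_neg2ll_at_cpp")]]
double lmm_neg2ll_at_cpp(SEXP xp, const arma::mat& Sigma, const double s2e) {
  Rcpp::XPtr<LmmData> d(xp);
  if (s2e <= 0.0) return R_PosInf;
  const int q = d->q;
  mat Srel = Sigma / s2e;
  mat L;
  if (!chol(L, Srel, "lower")) {
    if (!chol(L, mat(Srel + 1e-10 * eye(q, q)), "lower")) return R_PosInf;
  }
  Rcpp::List prof = profile_impl(d, L, false);
  if (Rcpp::as<bool>(prof["singular"])) return R_PosInf;
  double rss = Rcpp::as<double>(prof["rss"]);
  double logdet = Rcpp::as<double>(prof["logdet"]);
  return d->n * std::log(2.0 * M_PI * s2e) + logdet + rss / s2e;
}
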
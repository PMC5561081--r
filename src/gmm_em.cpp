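// Bivariate Gaussian mixture EM, mixmod-style initialization:
// means start at caller-chosen data points, proportions uniform,
// covariances at the pooled MLE covariance. Written for the tight inner
// loop of all-pairs network construction (millions of small fits), so the
// E/M steps are explicit loops with one exp() per point/component.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double LOG2PI = std::log(2.0 * M_PI);

static inline double det2(const mat& S) {
  return S(0, 0) * S(1, 1) - S(0, 1) * S(1, 0);
}

static inline mat inv2(const mat& S, double d) {
  mat out(2, 2);
  out(0, 0) =  S(1, 1) / d;
  out(1, 1) =  S(0, 0) / d;
  out(0, 1) = -S(0, 1) / d;
  out(1, 0) = -S(1, 0) / d;
  return out;
}

// add jitter to near-singular covariances; returns false if hopeless
static bool regularize(mat& S, double pooled_var) {
  if (det2(S) < 1e-12) {
    S.diag() += 1e-6 * pooled_var;
  }
  return det2(S) >= 1e-12;
}

// constrain covariances to the "free volume, common shape/orientation"
// family: Sigma_k = lambda_k * C with det(C) = 1
static bool constrain_pk_Lk_C(cube& covs, const vec& nk, double pooled_var) {
  int K = covs.n_slices;
  cube W(2, 2, K);
  vec lambda(K);
  for (int k = 0; k < K; ++k) {
    W.slice(k) = covs.slice(k) * nk(k); // scatter matrices
    double d = det2(covs.slice(k));
    lambda(k) = (d > 0) ? std::sqrt(d) : pooled_var;
    if (lambda(k) <= 0) lambda(k) = pooled_var;
  }
  mat C(2, 2);
  for (int it = 0; it < 3; ++it) {
    C.zeros();
    for (int k = 0; k < K; ++k) C += W.slice(k) / lambda(k);
    double dC = det2(C);
    if (dC <= 0) return false;
    C /= std::sqrt(dC); // det(C) = 1
    mat Cinv = inv2(C, det2(C));
    for (int k = 0; k < K; ++k) {
      lambda(k) = trace(Cinv * W.slice(k)) / (2.0 * nk(k));
      if (lambda(k) < 1e-12) lambda(k) = 1e-6 * pooled_var;
    }
  }
  for (int k = 0; k < K; ++k) covs.slice(k) = lambda(k) * C;
  return true;
}

struct EmResult {
  bool singular = true;
  bool converged = false;
  vec p;
  mat mu;
  cube covs;
  mat resp;
  std::vector<double> trace_ll;
};

static const int K_CAP = 16;

static void em_core(const mat& X, int K, const uvec& init_idx, int family,
                    int max_iter, double tol, EmResult& out) {
  const int N = X.n_rows;
  const double* x0 = X.colptr(0);
  const double* x1 = X.colptr(1);

  out.singular = true;
  out.converged = false;
  out.trace_ll.clear();
  if (K > K_CAP) return;

  vec p(K, fill::value(1.0 / K));
  mat mu(2, K);
  for (int k = 0; k < K; ++k) mu.col(k) = X.row(init_idx(k)).t();

  rowvec xbar = mean(X, 0);
  mat pooled(2, 2, fill::zeros);
  for (int i = 0; i < N; ++i) {
    double dx = x0[i] - xbar(0), dy = x1[i] - xbar(1);
    pooled(0, 0) += dx * dx;
    pooled(0, 1) += dx * dy;
    pooled(1, 1) += dy * dy;
  }
  pooled(1, 0) = pooled(0, 1);
  pooled /= N;
  double pooled_var = 0.5 * (pooled(0, 0) + pooled(1, 1));
  if (pooled_var <= 0) pooled_var = 1e-8;
  if (!regularize(pooled, pooled_var)) return;

  cube covs(2, 2, K);
  for (int k = 0; k < K; ++k) covs.slice(k) = pooled;

  // per-component constants of the current E-step, on the stack
  double s00[K_CAP], s01[K_CAP], s11[K_CAP], m0[K_CAP], m1[K_CAP],
         cst[K_CAP], ld[K_CAP], es[K_CAP];
  // weighted moment accumulators of the fused M-step
  double a_w[K_CAP], a_x[K_CAP], a_y[K_CAP], a_xx[K_CAP], a_xy[K_CAP],
         a_yy[K_CAP];

  bool singular = false;
  double ll_prev = -datum::inf;

  for (int iter = 0; iter < max_iter; ++iter) {
    for (int k = 0; k < K; ++k) {
      double d = det2(covs.slice(k));
      if (d < 1e-300 || p(k) <= 0) { singular = true; break; }
      mat Sinv = inv2(covs.slice(k), d);
      s00[k] = Sinv(0, 0);
      s01[k] = Sinv(0, 1);
      s11[k] = Sinv(1, 1);
      m0[k] = mu(0, k);
      m1[k] = mu(1, k);
      cst[k] = std::log(p(k)) - LOG2PI - 0.5 * std::log(d);
      a_w[k] = a_x[k] = a_y[k] = a_xx[k] = a_xy[k] = a_yy[k] = 0.0;
    }
    if (singular) break;

    // fused pass: log-densities, responsibilities, and the M-step moments
    double ll = 0.0;
    for (int i = 0; i < N; ++i) {
      const double xi = x0[i], yi = x1[i];
      double mx = -datum::inf;
      for (int k = 0; k < K; ++k) {
        const double dx = xi - m0[k], dy = yi - m1[k];
        const double v = cst[k] - 0.5 * (s00[k] * dx * dx +
                                         2.0 * s01[k] * dx * dy +
                                         s11[k] * dy * dy);
        ld[k] = v;
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int k = 0; k < K; ++k) {
        const double e = std::exp(ld[k] - mx);
        es[k] = e;
        s += e;
      }
      ll += mx + std::log(s);
      const double inv_s = 1.0 / s;
      for (int k = 0; k < K; ++k) {
        const double w = es[k] * inv_s;
        a_w[k] += w;
        a_x[k] += w * xi;
        a_y[k] += w * yi;
        a_xx[k] += w * xi * xi;
        a_xy[k] += w * xi * yi;
        a_yy[k] += w * yi * yi;
      }
    }
    out.trace_ll.push_back(ll);
    if (iter > 0 &&
        std::fabs(ll - ll_prev) < tol * (std::fabs(ll_prev) + 1e-10)) {
      out.converged = true;
      break;
    }
    ll_prev = ll;

    // M-step from the accumulated moments
    vec nk(K);
    for (int k = 0; k < K; ++k) {
      const double sw = a_w[k];
      if (sw < 1e-8) { singular = true; break; }
      nk(k) = sw;
      p(k) = sw / N;
      const double mxk = a_x[k] / sw, myk = a_y[k] / sw;
      mu(0, k) = mxk;
      mu(1, k) = myk;
      mat& S = covs.slice(k);
      S(0, 0) = a_xx[k] / sw - mxk * mxk;
      S(0, 1) = S(1, 0) = a_xy[k] / sw - mxk * myk;
      S(1, 1) = a_yy[k] / sw - myk * myk;
      if (!regularize(S, pooled_var)) { singular = true; break; }
    }
    if (singular) break;
    if (family == 1) {
      if (!constrain_pk_Lk_C(covs, nk, pooled_var)) { singular = true; break; }
      for (int k = 0; k < K; ++k) {
        if (!regularize(covs.slice(k), pooled_var)) { singular = true; break; }
      }
      if (singular) break;
    }
  }

  if (singular || out.trace_ll.empty()) return;

  // one final pass materializes the responsibilities of the returned params
  mat resp(N, K);
  for (int k = 0; k < K; ++k) {
    double d = det2(covs.slice(k));
    if (d < 1e-300) return;
    mat Sinv = inv2(covs.slice(k), d);
    s00[k] = Sinv(0, 0);
    s01[k] = Sinv(0, 1);
    s11[k] = Sinv(1, 1);
    m0[k] = mu(0, k);
    m1[k] = mu(1, k);
    cst[k] = std::log(p(k)) - LOG2PI - 0.5 * std::log(d);
  }
  for (int i = 0; i < N; ++i) {
    const double xi = x0[i], yi = x1[i];
    double mx = -datum::inf;
    for (int k = 0; k < K; ++k) {
      const double dx = xi - m0[k], dy = yi - m1[k];
      const double v = cst[k] - 0.5 * (s00[k] * dx * dx +
                                       2.0 * s01[k] * dx * dy +
                                       s11[k] * dy * dy);
      ld[k] = v;
      if (v > mx) mx = v;
    }
    double s = 0.0;
    for (int k = 0; k < K; ++k) {
      const double e = std::exp(ld[k] - mx);
      es[k] = e;
      s += e;
    }
    const double inv_s = 1.0 / s;
    for (int k = 0; k < K; ++k) resp(i, k) = es[k] * inv_s;
  }

  out.singular = false;
  out.p = p;
  out.mu = mu;
  out.covs = covs;
  out.resp = resp;
}

static Rcpp::List result_to_list(const EmResult& r) {
  if (r.singular) return Rcpp::List::create(Rcpp::Named("singular") = true);
  return Rcpp::List::create(
    Rcpp::Named("singular") = false,
    Rcpp::Named("converged") = r.converged,
    Rcpp::Named("proportions") = r.p,
    Rcpp::Named("means") = r.mu,
    Rcpp::Named("covariances") = r.covs,
    Rcpp::Named("responsibilities") = r.resp,
    Rcpp::Named("log_likelihood") = r.trace_ll.back(),
    Rcpp::Named("loglik_trace") = r.trace_ll);
}

// [[Rcpp::export]]
Rcpp::List em_fit_cpp(const arma::mat& X, int K,
                      const arma::uvec& init_idx, int family,
                      int max_iter, double tol) {
  EmResult r;
  em_core(X, K, init_idx, family, max_iter, tol, r);
  return result_to_list(r);
}

// Run the whole model scan for one pair: for each K (given by the length
// of each init vector) keep the best-log-likelihood run; return one
// result per K (NULL where every run collapsed).
// [[Rcpp::export]]
Rcpp::List select_scan_cpp(const arma::mat& X, Rcpp::List inits,
                           Rcpp::IntegerVector run_K, int family,
                           int max_iter, double tol) {
  int K_max = 0;
  for (int r = 0; r < run_K.size(); ++r) {
    if (run_K[r] > K_max) K_max = run_K[r];
  }
  std::vector<EmResult> best(K_max);
  std::vector<double> best_ll(K_max, -datum::inf);
  EmResult cur;
  for (int r = 0; r < run_K.size(); ++r) {
    int K = run_K[r];
    uvec idx = Rcpp::as<uvec>(inits[r]);
    em_core(X, K, idx, family, max_iter, tol, cur);
    if (!cur.singular && cur.trace_ll.back() > best_ll[K - 1]) {
      best_ll[K - 1] = cur.trace_ll.back();
      best[K - 1] = cur;
    }
  }
  Rcpp::List out(K_max);
  for (int k = 0; k < K_max; ++k) {
    out[k] = best[k].singular ? R_NilValue : (SEXP)result_to_list(best[k]);
  }
  return out;
}
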
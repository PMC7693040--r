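#include <Rcpp.h>
using namespace Rcpp;

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// Weighted elastic net path by cyclic coordinate descent with warm starts.
// X: n x p, columns standardized so that (1/n) x_j'x_j = 1; y centered.
// Objective: (1/2n)||y - X b||^2 + lambda * sum_j pf_j [a|b_j| + (1-a) b_j^2 / 2].
// Returns p x nlambda coefficient matrix on the standardized scale.
// [[Rcpp::export]]
NumericMatrix cd_enet_path(const NumericMatrix& X, const NumericVector& y,
                           const NumericVector& lambda, double alpha,
                           const NumericVector& pf, double tol, int maxit) {
  const int n = X.nrow(), p = X.ncol(), nl = lambda.size();
  NumericMatrix B(p, nl);
  std::vector<double> beta(p, 0.0), r(y.begin(), y.end());

  for (int l = 0; l < nl; ++l) {
    const double lam = lambda[l];
    for (int it = 0; it < maxit; ++it) {
      double dmax = 0.0;
      for (int j = 0; j < p; ++j) {
        const double* xj = &X(0, j);
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += xj[i] * r[i];
        rho = rho / n + beta[j];
        const double thr = lam * alpha * pf[j];
        const double denom = 1.0 + lam * (1.0 - alpha) * pf[j];
        const double bnew = soft(rho, thr) / denom;
        const double d = bnew - beta[j];
        if (d != 0.0) {
          for (int i = 0; i < n; ++i) r[i] -= xj[i] * d;
          beta[j] = bnew;
          const double ad = std::fabs(d);
          if (ad > dmax) dmax = ad;
        }
      }
      if (dmax < tol) break;
    }
    for (int j = 0; j < p; ++j) B(j, l) = beta[j];
  }
  return B;
}

// Cross-tissue sparse group lasso by block coordinate descent.
// Xs: list of n_t x p matrices (columns standardized per tissue, (1/n_t)x'x=1),
// ys: list of centered response vectors. Objective:
//   sum_t (1/2 n_t)||y_t - X_t b_t||^2 + l1 sum_tj |b_tj| + l2 sum_j ||b_j.||_2.
// Block update over variants j is the exact prox because the per-tissue
// quadratic curvature is 1 after standardization.
// [[Rcpp::export]]
List cd_ctimp(const List& Xs, const List& ys, double l1, double l2,
              double tol, int maxit, NumericMatrix beta0) {
  const int T = Xs.size();
  std::vector<NumericMatrix> X(T);
  std::vector<NumericVector> y(T);
  for (int t = 0; t < T; ++t) { X[t] = as<NumericMatrix>(Xs[t]); y[t] = as<NumericVector>(ys[t]); }
  const int p = X[0].ncol();
  NumericMatrix beta(clone(beta0)); // p x T
  std::vector< std::vector<double> > r(T);
  for (int t = 0; t < T; ++t) {
    const int n = X[t].nrow();
    r[t].assign(y[t].begin(), y[t].end());
    for (int j = 0; j < p; ++j) {
      const double b = beta(j, t);
      if (b != 0.0) { const double* xj = &X[t](0, j); for (int i = 0; i < n; ++i) r[t][i] -= xj[i] * b; }
    }
  }

  auto objective = [&]() {
    double obj = 0.0;
    for (int t = 0; t < T; ++t) {
      const int n = X[t].nrow();
      double ss = 0.0;
      for (int i = 0; i < n; ++i) ss += r[t][i] * r[t][i];
      obj += ss / (2.0 * n);
    }
    for (int j = 0; j < p; ++j) {
      double g = 0.0;
      for (int t = 0; t < T; ++t) { obj += l1 * std::fabs(beta(j, t)); g += beta(j, t) * beta(j, t); }
      obj += l2 * std::sqrt(g);
    }
    return obj;
  };

  std::vector<double> trace;
  trace.push_back(objective());
  int it = 0;
  for (; it < maxit; ++it) {
    double dmax = 0.0;
    for (int j = 0; j < p; ++j) {
      std::vector<double> u(T), bt(T);
      for (int t = 0; t < T; ++t) {
        const int n = X[t].nrow();
        const double* xj = &X[t](0, j);
        double rho = 0.0;
        for (int i = 0; i < n; ++i) rho += xj[i] * r[t][i];
        u[t] = rho / n + beta(j, t);
        bt[t] = soft(u[t], l1);
      }
      double g = 0.0;
      for (int t = 0; t < T; ++t) g += bt[t] * bt[t];
      g = std::sqrt(g);
      const double shrink = (g > 0.0) ? std::max(0.0, 1.0 - l2 / g) : 0.0;
      for (int t = 0; t < T; ++t) {
        const double bnew = bt[t] * shrink;
        const double d = bnew - beta(j, t);
        if (d != 0.0) {
          const int n = X[t].nrow();
          const double* xj = &X[t](0, j);
          for (int i = 0; i < n; ++i) r[t][i] -= xj[i] * d;
          beta(j, t) = bnew;
          const double ad = std::fabs(d);
          if (ad > dmax) dmax = ad;
        }
      }
    }
    trace.push_back(objective());
    const size_t m = trace.size();
    const double rel = std::fabs(trace[m - 2] - trace[m - 1]) /
                       (std::fabs(trace[m - 2]) + 1e-12);
    if (dmax < tol || rel < tol) break;
  }
  return List::create(_["beta"] = beta,
                      _["objective_trace"] = wrap(trace),
                      _["iterations"] = it + 1,
                      _["converged"] = it < maxit);
}
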
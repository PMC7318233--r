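#include <Rcpp.h>
using namespace Rcpp;

// Graphical lasso by the block coordinate-descent algorithm of Friedman,
// Hastie & Tibshirani (2008): each column of the working covariance W is
// updated by solving a lasso problem on the Gram matrix W11 with response
// s12, via cyclic coordinate descent with soft-thresholding. The L1
// penalty applies to off-diagonal precision entries only, so diag(W)
// stays at diag(S). Warm starts (W, Beta from a previous lambda) make a
// decreasing penalty path cheap.

static inline double soft(double z, double t) {
  if (z > t) return z - t;
  if (z < -t) return z + t;
  return 0.0;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(NumericMatrix S, double lambda, double tol, int maxit,
                Nullable<NumericMatrix> W_init = R_NilValue,
                Nullable<NumericMatrix> Beta_init = R_NilValue) {
  const int p = S.nrow();
  NumericMatrix W(p, p), Beta(p, p);
  if (W_init.isNotNull()) {
    W = clone(NumericMatrix(W_init));
  } else {
    for (int i = 0; i < p; ++i)
      for (int j = 0; j < p; ++j) W(i, j) = S(i, j);
  }
  if (Beta_init.isNotNull()) Beta = clone(NumericMatrix(Beta_init));
  for (int j = 0; j < p; ++j) W(j, j) = S(j, j);  // diagonal unpenalized

  std::vector<int> idx(p - 1);
  int outer_it = 0;
  bool converged = (p == 1);
  for (outer_it = 0; outer_it < maxit && !converged; ++outer_it) {
    double max_dw = 0.0;
    for (int j = 0; j < p; ++j) {
      int m = 0;
      for (int t = 0; t < p; ++t) if (t != j) idx[m++] = t;
      // inner lasso: minimize 0.5 b'W11 b - s12'b + lambda |b|_1
      for (int inner = 0; inner < maxit; ++inner) {
        double max_db = 0.0;
        for (int a = 0; a < p - 1; ++a) {
          const int k = idx[a];
          double grad = S(k, j);
          for (int b = 0; b < p - 1; ++b) {
            const int l = idx[b];
            if (l != k) grad -= W(k, l) * Beta(l, j);
          }
          const double bnew = soft(grad, lambda) / W(k, k);
          const double db = std::abs(bnew - Beta(k, j));
          if (db > max_db) max_db = db;
          Beta(k, j) = bnew;
        }
        if (max_db < tol) break;
      }
      for (int a = 0; a < p - 1; ++a) {
        const int k = idx[a];
        double w = 0.0;
        for (int b = 0; b < p - 1; ++b) w += W(k, idx[b]) * Beta(idx[b], j);
        const double dw = std::abs(w - W(k, j));
        if (dw > max_dw) max_dw = dw;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_dw < tol) converged = true;
  }

  // recover the precision matrix from W and the regression coefficients
  NumericMatrix Theta(p, p);
  for (int j = 0; j < p; ++j) {
    double q = W(j, j);
    for (int k = 0; k < p; ++k) if (k != j) q -= W(k, j) * Beta(k, j);
    const double tjj = 1.0 / q;
    Theta(j, j) = tjj;
    for (int k = 0; k < p; ++k)
      if (k != j) Theta(k, j) = (Beta(k, j) == 0.0) ? 0.0 : -Beta(k, j) * tjj;
  }
  // enforce exact symmetry, preserving exact zeros
  for (int j = 0; j < p; ++j)
    for (int k = j + 1; k < p; ++k) {
      if (Theta(j, k) == 0.0 || Theta(k, j) == 0.0) {
        Theta(j, k) = Theta(k, j) = 0.0;
      } else {
        const double v = 0.5 * (Theta(j, k) + Theta(k, j));
        Theta(j, k) = Theta(k, j) = v;
      }
    }

  return List::create(_["precision"] = Theta, _["covariance"] = W,
                      _["beta"] = Beta, _["iterations"] = outer_it,
                      _["converged"] = converged);
}
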
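// Graphical lasso via block coordinate descent (Friedman-Hastie-Tibshirani
// style) with an unpenalized diagonal, plus a path driver with warm starts.
// The inner lasso is plain cyclic coordinate descent with soft-thresholding,
// so off-diagonal precision entries excluded by the penalty are exact zeros.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One full glasso solve at penalty rho, warm-started from W and B (p x p
// matrix of lasso coefficients, column j holding beta for column-problem j
// with a structural zero at row j). Returns false if not converged.
static bool glasso_solve(const mat& S, double rho, mat& W, mat& B,
                         int maxit, double tol, int lasso_maxit) {
  const uword p = S.n_rows;
  const double thr = tol * mean(mean(abs(S - diagmat(S.diag())))) + 1e-14;
  bool converged = false;

  vec g(p);
  for (int it = 0; it < maxit; ++it) {
    double dw = 0.0;
    for (uword j = 0; j < p; ++j) {
      // lasso on column j: 0.5 b' W11 b - b' s12 + rho |b|_1
      // maintain g_k = s12_k - sum_{l != j} W_kl * b_l incrementally
      for (uword k = 0; k < p; ++k) {
        double acc = S(k, j);
        for (uword l = 0; l < p; ++l)
          if (l != j && B(l, j) != 0.0) acc -= W(k, l) * B(l, j);
        g[k] = acc;
      }
      for (int lit = 0; lit < lasso_maxit; ++lit) {
        double db = 0.0;
        for (uword k = 0; k < p; ++k) {
          if (k == j) continue;
          double bold = B(k, j);
          double bnew = soft(g[k] + W(k, k) * bold, rho) / W(k, k);
          if (bnew == bold) continue;
          double delta = bnew - bold;
          db = std::max(db, std::fabs(delta));
          B(k, j) = bnew;
          for (uword l = 0; l < p; ++l) g[l] -= W(l, k) * delta;
        }
        if (db < thr) break;
      }
      // w12 = W11 * beta = s12 - g
      for (uword k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = S(k, j) - g[k];
        dw = std::max(dw, std::fabs(w - W(k, j)));
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (dw < thr) { converged = true; break; }
  }
  return converged;
}

// Recover the precision matrix from (W, B).
static mat recover_K(const mat& W, const mat& B) {
  const uword p = W.n_rows;
  mat K(p, p, fill::zeros);
  for (uword j = 0; j < p; ++j) {
    double q = W(j, j);
    for (uword l = 0; l < p; ++l) {
      if (l == j) continue;
      q -= W(j, l) * B(l, j);
    }
    double kjj = 1.0 / q;
    K(j, j) = kjj;
    for (uword k = 0; k < p; ++k) {
      if (k == j) continue;
      // exact zero of beta => exact zero of K off-diagonal
      K(k, j) = (B(k, j) == 0.0) ? 0.0 : -B(k, j) * kjj;
    }
  }
  // symmetrize (numerically) while preserving exact zeros
  for (uword j = 0; j < p; ++j)
    for (uword k = j + 1; k < p; ++k) {
      if (K(k, j) == 0.0 || K(j, k) == 0.0) { K(k, j) = 0.0; K(j, k) = 0.0; }
      else { double v = 0.5 * (K(k, j) + K(j, k)); K(k, j) = v; K(j, k) = v; }
    }
  return K;
}

// [[Rcpp::export]]
Rcpp::List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                           int maxit = 200, double tol = 1e-6,
                           int lasso_maxit = 200) {
  const uword p = S.n_rows;
  const uword nl = lambdas.n_elem;
  // lambdas assumed sorted descending for warm starts
  mat W = S;
  mat B(p, p, fill::zeros);
  cube Ks(p, p, nl);
  Rcpp::LogicalVector conv(nl);
  for (uword i = 0; i < nl; ++i) {
    conv[i] = glasso_solve(S, lambdas[i], W, B, maxit, tol, lasso_maxit);
    Ks.slice(i) = recover_K(W, B);
  }
  return Rcpp::List::create(Rcpp::Named("K") = Ks,
                            Rcpp::Named("converged") = conv);
}
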
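// l1-penalized precision matrix estimation (graphical lasso) by block
// coordinate descent: maximize  log det(Omega) - trace(S Omega) - lam ||Omega||_1
// (diagonal penalized). Each column update solves a lasso subproblem on the
// current working covariance W by cyclic coordinate descent; warm starts are
// used along a penalty path.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// one glasso fit; W and Beta carry warm-start state in/out
static void glasso_core(const arma::mat &S, double lam, double thr,
                        int max_iter, arma::mat &W, arma::mat &Beta,
                        bool &converged) {
  const int p = S.n_rows;
  converged = true;
  if (p == 1) { W(0, 0) = S(0, 0) + lam; return; }

  // scale-aware convergence threshold (mean |off-diagonal S|)
  double offsum = 0.0;
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < p; ++i) if (i != j) offsum += std::fabs(S(i, j));
  double thr_abs = thr * std::max(offsum / (p * (p - 1)), 1e-12);

  for (int j = 0; j < p; ++j) W(j, j) = S(j, j) + lam;

  for (int iter = 0; iter < max_iter; ++iter) {
    double max_change = 0.0;
    for (int j = 0; j < p; ++j) {
      // lasso: min 1/2 b' W11 b - s12' b + lam |b|_1
      arma::vec beta = Beta.col(j);          // length p, entry j unused (0)
      for (int inner = 0; inner < 200; ++inner) {
        double dmax = 0.0;
        for (int k = 0; k < p; ++k) {
          if (k == j) continue;
          double grad = S(k, j);
          for (int l = 0; l < p; ++l) {
            if (l == j || l == k) continue;
            grad -= W(k, l) * beta(l);
          }
          double bnew = soft(grad, lam) / W(k, k);
          double ch = std::fabs(bnew - beta(k));
          if (ch > dmax) dmax = ch;
          beta(k) = bnew;
        }
        if (dmax < 1e-3 * thr_abs) break;
      }
      Beta.col(j) = beta;
      // w12 = W11 beta
      for (int k = 0; k < p; ++k) {
        if (k == j) continue;
        double w = 0.0;
        for (int l = 0; l < p; ++l) {
          if (l == j) continue;
          w += W(k, l) * beta(l);
        }
        double ch = std::fabs(w - W(k, j));
        if (ch > max_change) max_change = ch;
        W(k, j) = w;
        W(j, k) = w;
      }
    }
    if (max_change < thr_abs) return;
  }
  converged = false;
}

// recover Omega from converged (W, Beta)
static arma::mat recover_omega(const arma::mat &W, const arma::mat &Beta) {
  const int p = W.n_rows;
  arma::mat Omega(p, p, arma::fill::zeros);
  for (int j = 0; j < p; ++j) {
    double dot = 0.0;
    for (int k = 0; k < p; ++k) if (k != j) dot += W(k, j) * Beta(k, j);
    double ojj = 1.0 / (W(j, j) - dot);
    Omega(j, j) = ojj;
    for (int k = 0; k < p; ++k)
      if (k != j) Omega(k, j) = -Beta(k, j) * ojj;
  }
  // symmetrize; preserve exact zeros where both directions agree on zero
  arma::mat Sym = 0.5 * (Omega + Omega.t());
  for (int j = 0; j < p; ++j)
    for (int k = 0; k < j; ++k)
      if (Omega(k, j) == 0.0 && Omega(j, k) == 0.0) { Sym(k, j) = 0.0; Sym(j, k) = 0.0; }
  return Sym;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
List glasso_cpp(const arma::mat &S, double lam, double thr = 1e-6,
                int max_iter = 500) {
  const int p = S.n_rows;
  arma::mat W = S;
  arma::mat Beta(p, p, arma::fill::zeros);
  bool conv;
  glasso_core(S, lam, thr, max_iter, W, Beta, conv);
  arma::mat Omega = recover_omega(W, Beta);
  return List::create(_["omega"] = Omega, _["w"] = W, _["converged"] = conv);
}

// path version with warm starts; lambdas must be decreasing
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(const arma::mat &S, const arma::vec &lambdas,
                     double thr = 1e-6, int max_iter = 500) {
  const int p = S.n_rows;
  const int L = lambdas.n_elem;
  arma::mat W = S;
  arma::mat Beta(p, p, arma::fill::zeros);
  arma::cube omegas(p, p, L);
  LogicalVector conv(L);
  for (int l = 0; l < L; ++l) {
    bool c;
    glasso_core(S, lambdas(l), thr, max_iter, W, Beta, c);
    conv[l] = c;
    omegas.slice(l) = recover_omega(W, Beta);
  }
  return List::create(_["omegas"] = omegas, _["converged"] = conv);
}
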
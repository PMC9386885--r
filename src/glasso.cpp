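// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

// Graphical lasso by blockwise coordinate descent (Friedman, Hastie &
// Tibshirani 2008). For each column j the working covariance W is
// partitioned and the subproblem
//     min_b  1/2 b' W11 b - s12' b + rho ||b||_1
// is solved by cyclic coordinate descent with soft-thresholding; W and the
// regression coefficients are swept until the covariance stabilizes. The
// precision matrix is recovered from the final coefficients. The penalty
// applies to off-diagonal entries; the diagonal carries the usual
// W_jj = S_jj + rho inflation.

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

static void glasso_single(const arma::mat& S, double rho, arma::mat& W,
                          arma::mat& B, int maxit, double tol) {
  int p = S.n_rows;
  double off_mean = arma::accu(arma::abs(S - arma::diagmat(S.diag()))) /
                    std::max(1, p * (p - 1));
  double thr = tol * off_mean;
  if (thr <= 0) thr = tol;

  for (int it = 0; it < maxit; it++) {
    double dw = 0.0;
    for (int j = 0; j < p; j++) {
      arma::uvec idx(p - 1);
      int t = 0;
      for (int i = 0; i < p; i++) if (i != j) idx[t++] = i;
      arma::mat W11 = W.submat(idx, idx);
      arma::vec s12 = S.col(j);
      s12 = s12.elem(idx);
      arma::vec beta = B.col(j);
      beta = beta.elem(idx);

      // lasso subproblem by coordinate descent
      for (int init = 0; init < 200; init++) {
        double dmax = 0.0;
        for (int l = 0; l < p - 1; l++) {
          double old = beta[l];
          double r = s12[l] - (arma::dot(W11.row(l), beta) - W11(l, l) * old);
          double bnew = soft(r, rho) / W11(l, l);
          if (bnew != old) {
            beta[l] = bnew;
            double d = std::fabs(bnew - old);
            if (d > dmax) dmax = d;
          }
        }
        if (dmax < 1e-8) break;
      }

      arma::vec w12 = W11 * beta;
      for (int l = 0; l < p - 1; l++) {
        double d = std::fabs(W(idx[l], j) - w12[l]);
        if (d > dw) dw = d;
        W(idx[l], j) = w12[l];
        W(j, idx[l]) = w12[l];
        B(idx[l], j) = beta[l];
      }
    }
    if (dw < thr) break;
  }
}

//' @noRd
// [[Rcpp::export(name = ".glasso_path_cpp")]]
List glasso_path_cpp(const arma::mat& S, const arma::vec& lambdas,
                     int maxit = 100, double tol = 1e-4) {
  int p = S.n_rows;
  int nl = lambdas.n_elem;
  // warm start along a decreasing penalty path
  arma::uvec ord = arma::sort_index(lambdas, "descend");
  arma::mat W = S;
  arma::mat B(p, p, arma::fill::zeros);
  arma::cube K(p, p, nl);

  for (int q = 0; q < nl; q++) {
    int m = ord[q];
    double rho = lambdas[m];
    W.diag() = S.diag() + rho;
    glasso_single(S, rho, W, B, maxit, tol);

    // precision from the regression coefficients
    arma::mat Theta(p, p, arma::fill::zeros);
    for (int j = 0; j < p; j++) {
      arma::uvec idx(p - 1);
      int t = 0;
      for (int i = 0; i < p; i++) if (i != j) idx[t++] = i;
      arma::vec beta = B.col(j);
      beta = beta.elem(idx);
      arma::vec w12 = W.col(j);
      w12 = w12.elem(idx);
      double t22 = 1.0 / (W(j, j) - arma::dot(w12, beta));
      Theta(j, j) = t22;
      for (int l = 0; l < p - 1; l++) Theta(idx[l], j) = -beta[l] * t22;
    }
    Theta = (Theta + Theta.t()) / 2.0;
    K.slice(m) = Theta;
  }
  return List::create(Named("precision") = K);
}
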
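// Graphical lasso by blockwise coordinate descent (Friedman-style), with the
// diagonal of the precision matrix left unpenalized, and a warm-started
// lambda path with EBIC scoring used for model selection.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double soft(double x, double t) {
  if (x > t) return x - t;
  if (x < -t) return x + t;
  return 0.0;
}

// One glasso solve. S must be symmetric with positive diagonal.
// Returns the estimated covariance W, precision K, and the regression
// coefficient matrix B (column j holds beta for block j) used to build K.
static void glasso_solve(const mat& S, double lambda, double tol, int maxit,
                         mat& W, mat& K, bool& converged, int& niter) {
  const uword p = S.n_rows;
  if (p == 1) {
    W = S; K = mat(1, 1); K(0, 0) = 1.0 / S(0, 0);
    converged = true; niter = 0;
    return;
  }
  if (W.n_rows != p) W = S;           // cold start: W = S (diag unpenalized)
  W.diag() = S.diag();
  mat B(p - 1, p, fill::zeros);       // per-column lasso coefficients
  // warm start B from W if provided by caller via previous solution: start 0.

  double thr = tol * mean(mean(abs(S - diagmat(S.diag())))); // scale-aware
  if (thr <= 0) thr = tol;
  converged = false;
  int it = 0;
  for (it = 0; it < maxit; ++it) {
    double dmax = 0.0;
    for (uword j = 0; j < p; ++j) {
      uvec idx(p - 1);
      uword c = 0;
      for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
      mat W11 = W(idx, idx);
      vec s12 = S.col(j); s12 = s12(idx);
      vec beta = B.col(j);
      // lasso coordinate descent: min 1/2 b'W11 b - s12'b + lambda |b|_1
      for (int inner = 0; inner < 1000; ++inner) {
        double del = 0.0;
        for (uword k = 0; k < p - 1; ++k) {
          double g = s12(k) - dot(W11.col(k), beta) + W11(k, k) * beta(k);
          double bnew = soft(g, lambda) / W11(k, k);
          double d = std::abs(bnew - beta(k));
          if (d > del) del = d;
          beta(k) = bnew;
        }
        if (del < thr * 0.1) break;
      }
      B.col(j) = beta;
      vec w12 = W11 * beta;
      for (uword k = 0; k < p - 1; ++k) {
        double d = std::abs(W(idx(k), j) - w12(k));
        if (d > dmax) dmax = d;
        W(idx(k), j) = w12(k);
        W(j, idx(k)) = w12(k);
      }
    }
    if (dmax < thr) { converged = true; ++it; break; }
  }
  niter = it;
  // recover K from the final B and W
  K.set_size(p, p);
  for (uword j = 0; j < p; ++j) {
    uvec idx(p - 1);
    uword c = 0;
    for (uword k = 0; k < p; ++k) if (k != j) idx(c++) = k;
    vec beta = B.col(j);
    vec w12 = W.col(j); w12 = w12(idx);
    double k22 = 1.0 / (W(j, j) - dot(w12, beta));
    K(j, j) = k22;
    for (uword k = 0; k < p - 1; ++k) K(idx(k), j) = -beta(k) * k22;
  }
  // exact zeros survive symmetrization: both directions are zero iff the
  // lasso zeroed them; average tidies tiny asymmetries in nonzero entries
  mat Ks = 0.5 * (K + K.t());
  for (uword i = 0; i < p; ++i)
    for (uword j = 0; j < p; ++j)
      if (i != j && (K(i, j) == 0.0 || K(j, i) == 0.0)) Ks(i, j) = 0.0;
  K = Ks;
}

// [[Rcpp::export(name = ".glasso_cpp")]]
Rcpp::List glasso_cpp(const arma::mat& S, double lambda,
                      double tol = 1e-8, int maxit = 1000) {
  mat W, K;
  bool conv; int niter;
  W.reset();
  glasso_solve(S, lambda, tol, maxit, W, K, conv, niter);
  return Rcpp::List::create(Rcpp::Named("w") = W,
                            Rcpp::Named("wi") = K,
                            Rcpp::Named("converged") = conv,
                            Rcpp::Named("niter") = niter);
}

// Lambda path with warm starts; EBIC_gamma = -2*l + E*log(n) + 4*E*gamma*log(p)
// with l = (n/2) * (logdet K - tr(SK)); the 2*pi constant is omitted (it is
// constant along the path and cannot change the argmin).
// [[Rcpp::export(name = ".ebic_path_cpp")]]
Rcpp::List ebic_path_cpp(const arma::mat& S, double n, double gamma,
                         const arma::vec& lambdas,
                         double tol = 1e-8, int maxit = 1000) {
  const uword p = S.n_rows;
  const uword L = lambdas.n_elem;
  vec ebic(L), loglik(L);
  ivec ecount(L);
  mat W; W.reset();
  mat bestK, bestW;
  double best = datum::inf;
  int best_i = -1;
  for (uword i = 0; i < L; ++i) {
    mat K;
    bool conv; int niter;
    glasso_solve(S, lambdas(i), tol, maxit, W, K, conv, niter); // warm start W
    if (!conv) Rcpp::stop("graphical lasso did not converge at lambda = %g",
                          lambdas(i));
    int E = 0;
    for (uword a = 0; a < p; ++a)
      for (uword b = a + 1; b < p; ++b)
        if (K(a, b) != 0.0) ++E;
    double ld, sign;
    log_det(ld, sign, K);
    double ll = 0.5 * n * (ld - accu(S % K));
    double crit = -2.0 * ll + E * std::log(n) + 4.0 * E * gamma * std::log((double)p);
    ebic(i) = crit; loglik(i) = ll; ecount(i) = E;
    if (crit < best) { best = crit; best_i = (int)i; bestK = K; bestW = W; }
  }
  return Rcpp::List::create(Rcpp::Named("ebic") = ebic,
                            Rcpp::Named("loglik") = loglik,
                            Rcpp::Named("ecount") = ecount,
                            Rcpp::Named("best_index") = best_i + 1,
                            Rcpp::Named("wi") = bestK,
                            Rcpp::Named("w") = bestW);
}
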
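// NIPALS PLS1 core with cross-validation driver.
// X is deflated, y is not; y-loadings are recomputed against the current scores.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

// Fit on centered X, y. Returns number of components actually extracted and
// fills W (weights), P (x-loadings), q (y-loadings), T (scores).
int nipals_fit(const mat& X0, const vec& y0, int ncomp,
               mat& W, mat& P, vec& q, mat& T) {
  const uword p = X0.n_cols, n = X0.n_rows;
  mat X = X0;
  W.set_size(p, ncomp); P.set_size(p, ncomp);
  T.set_size(n, ncomp); q.set_size(ncomp);
  int used = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = X.t() * y0;
    double nw = norm(w, 2);
    if (nw < 1e-12) break;              // y fully explained / X exhausted
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pv = X.t() * t / tt;
    double qa = dot(y0, t) / tt;
    X -= t * pv.t();
    W.col(a) = w; P.col(a) = pv; T.col(a) = t; q(a) = qa;
    ++used;
  }
  return used;
}

// Regression coefficients for 1..used components: B = W (P'W)^{-1} q,
// evaluated incrementally so column k uses the first k components.
mat nipals_coefs(const mat& W, const mat& P, const vec& q, int used) {
  mat Wu = W.cols(0, used - 1);
  mat R = P.cols(0, used - 1).t() * Wu;  // unit upper triangular in exact arithmetic
  mat B(W.n_rows, used);
  for (int k = 1; k <= used; ++k) {
    vec z = solve(trimatu(R.submat(0, 0, k - 1, k - 1)), q.subvec(0, k - 1));
    B.col(k - 1) = Wu.cols(0, k - 1) * z;
  }
  return B;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List nipals_fit_cpp(const arma::mat& X, const arma::vec& y, int ncomp) {
  vec xmean = mean(X, 0).t();
  double ymean = mean(y);
  mat Xc = X.each_row() - xmean.t();
  vec yc = y - ymean;
  mat W, P, T; vec q;
  int used = nipals_fit(Xc, yc, ncomp, W, P, q, T);
  if (used == 0) {
    return Rcpp::List::create(
      Rcpp::Named("n_used") = 0,
      Rcpp::Named("x_mean") = xmean, Rcpp::Named("y_mean") = ymean);
  }
  mat B = nipals_coefs(W, P, q, used);
  return Rcpp::List::create(
    Rcpp::Named("n_used") = used,
    Rcpp::Named("weights") = W.cols(0, used - 1),
    Rcpp::Named("x_loadings") = P.cols(0, used - 1),
    Rcpp::Named("y_loadings") = q.subvec(0, used - 1),
    Rcpp::Named("scores") = T.cols(0, used - 1),
    Rcpp::Named("coefficients") = B,
    Rcpp::Named("x_mean") = xmean,
    Rcpp::Named("y_mean") = ymean);
}

// Cross-validated squared prediction error per held-out observation (rows)
// and candidate component count (columns).
// folds: 1-based fold id per row (LOO when all distinct).
// [[Rcpp::export]]
arma::mat plsr_cv_sqerr_cpp(const arma::mat& X, const arma::vec& y,
                            int ncomp, const arma::ivec& folds) {
  const uword n = X.n_rows;
  const int K = folds.max();
  mat sqerr(n, ncomp, fill::zeros);
  for (int f = 1; f <= K; ++f) {
    uvec test = find(folds == f);
    uvec train = find(folds != f);
    if (test.n_elem == 0) continue;
    mat Xtr = X.rows(train);
    vec ytr = y(train);
    vec xmean = mean(Xtr, 0).t();
    double ymean = mean(ytr);
    mat Xc = Xtr.each_row() - xmean.t();
    vec yc = ytr - ymean;
    int cap = std::min<int>(ncomp, std::min<uword>(train.n_elem - 1, X.n_cols));
    mat W, P, T; vec q;
    int used = nipals_fit(Xc, yc, cap, W, P, q, T);
    mat Xte = X.rows(test);
    Xte.each_row() -= xmean.t();
    if (used == 0) {
      for (int k = 0; k < ncomp; ++k)
        sqerr(test, uvec{static_cast<uword>(k)}) = square(y(test) - ymean);
      continue;
    }
    mat B = nipals_coefs(W, P, q, used);
    for (int k = 0; k < ncomp; ++k) {
      int kk = std::min(k, used - 1);   // component pool exhausted: reuse last
      vec pred = Xte * B.col(kk) + ymean;
      sqerr(test, uvec{static_cast<uword>(k)}) = square(y(test) - pred);
    }
  }
  return sqerr;
}
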
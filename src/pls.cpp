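// NIPALS PLS1 core and cross-validation loops.
//
// All entry points take the response and predictors uncentered; centering is
// done internally on the calibration rows only, so held-out rows never touch
// the centering statistics. Fold / calibration index sets are generated on the
// R side (seeded there) and passed down 1-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// NIPALS PLS1 on pre-centered data. Xc and yc are deflated in place.
// Returns the number of components actually extracted (may be < A when the
// residual covariance collapses below tol).
static int nipals_pls1(mat& Xc, vec& yc, int A, double tol,
                       mat& W, mat& P, vec& q) {
  int a = 0;
  for (; a < A; ++a) {
    vec w = Xc.t() * yc;
    double nw = norm(w, 2);
    if (nw < tol) break;
    w /= nw;
    vec t = Xc * w;
    double tt = dot(t, t);
    if (tt < tol) break;
    vec p = Xc.t() * t / tt;
    double qa = dot(yc, t) / tt;
    Xc -= t * p.t();
    yc -= qa * t;
    W.col(a) = w;
    P.col(a) = p;
    q(a) = qa;
  }
  return a;
}

// Regression coefficients in centered space for the first A components:
// b = W (P'W)^{-1} q, using the leading A columns.
static vec pls_coef(const mat& W, const mat& P, const vec& q, int A) {
  mat Wa = W.cols(0, A - 1);
  mat Pa = P.cols(0, A - 1);
  vec qa = q.subvec(0, A - 1);
  mat R = Pa.t() * Wa;  // upper triangular in exact arithmetic
  vec z = solve(trimatu(R), qa);
  return Wa * z;
}

// [[Rcpp::export(name = ".cpp_pls_fit")]]
Rcpp::List cpp_pls_fit(const arma::mat& X, const arma::vec& y,
                       int A, double tol) {
  int n = X.n_rows, p = X.n_cols;
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat W(p, A, fill::zeros), P(p, A, fill::zeros);
  vec q(A, fill::zeros);
  int a = nipals_pls1(Xc, yc, A, tol, W, P, q);
  vec b(p, fill::zeros);
  if (a > 0) b = pls_coef(W, P, q, a);
  return Rcpp::List::create(
      Rcpp::Named("x_mean") = xm.t(),
      Rcpp::Named("y_mean") = ym,
      Rcpp::Named("W") = W.cols(0, std::max(a, 1) - 1),
      Rcpp::Named("P") = P.cols(0, std::max(a, 1) - 1),
      Rcpp::Named("q") = q.subvec(0, std::max(a, 1) - 1),
      Rcpp::Named("b") = b,
      Rcpp::Named("A") = a);
}

// Predictions on Xtest for every component count 1..A (columns), given a
// training block. Uses sequential deflation of the test scores so no matrix
// inverse is needed per A.
static mat holdout_pred_curve(const mat& Xtr, const vec& ytr,
                              const mat& Xte, int A, double tol) {
  int p = Xtr.n_cols;
  rowvec xm = mean(Xtr, 0);
  double ym = mean(ytr);
  mat Xc = Xtr.each_row() - xm;
  vec yc = ytr - ym;
  mat W(p, A, fill::zeros), P(p, A, fill::zeros);
  vec q(A, fill::zeros);
  int a = nipals_pls1(Xc, yc, A, tol, W, P, q);
  mat Xtc = Xte.each_row() - xm;
  mat pred(Xte.n_rows, A);
  vec yhat(Xte.n_rows, fill::value(ym));
  for (int j = 0; j < A; ++j) {
    if (j < a) {
      vec t = Xtc * W.col(j);
      Xtc -= t * P.col(j).t();
      yhat += q(j) * t;
    }
    pred.col(j) = yhat;  // beyond rank support, curve stays flat
  }
  return pred;
}

// Pooled held-out squared error for each component count 1..A over k folds.
// foldid is 1-based fold membership per row.
// [[Rcpp::export(name = ".cpp_cv_sse")]]
Rcpp::List cpp_cv_sse(const arma::mat& X, const arma::vec& y,
                      const arma::ivec& foldid, int A, double tol) {
  int n = X.n_rows;
  int K = foldid.max();
  vec sse(A, fill::zeros);
  int n_out = 0;
  for (int k = 1; k <= K; ++k) {
    uvec te = find(foldid == k);
    uvec tr = find(foldid != k);
    if (te.n_elem == 0) continue;
    if (tr.n_elem < 2) Rcpp::stop("fold with fewer than 2 calibration samples");
    mat pred = holdout_pred_curve(X.rows(tr), y(tr), X.rows(te), A, tol);
    vec yte = y(te);
    for (int j = 0; j < A; ++j) {
      vec r = yte - pred.col(j);
      sse(j) += dot(r, r);
    }
    n_out += te.n_elem;
  }
  (void)n;
  return Rcpp::List::create(Rcpp::Named("sse") = sse,
                            Rcpp::Named("n_heldout") = n_out);
}

// Monte-Carlo CV: calmat holds one calibration draw per column (1-based row
// indices); held-out rows are the complement. Returns pooled squared errors
// per component count and the total held-out count.
// [[Rcpp::export(name = ".cpp_mccv_sse")]]
Rcpp::List cpp_mccv_sse(const arma::mat& X, const arma::vec& y,
                        const arma::imat& calmat, int A, double tol) {
  int n = X.n_rows;
  int R = calmat.n_cols;
  vec sse(A, fill::zeros);
  int n_out = 0;
  for (int r = 0; r < R; ++r) {
    std::vector<char> in_cal(n, 0);
    for (unsigned int i = 0; i < calmat.n_rows; ++i)
      in_cal[calmat(i, r) - 1] = 1;
    uvec tr(calmat.n_rows), te(n - calmat.n_rows);
    int a = 0, b = 0;
    for (int i = 0; i < n; ++i) (in_cal[i] ? tr(a++) : te(b++)) = i;
    if ((int)tr.n_elem < 2) Rcpp::stop("calibration draw smaller than 2 samples");
    if (te.n_elem == 0) continue;
    mat pred = holdout_pred_curve(X.rows(tr), y(tr), X.rows(te), A, tol);
    vec yte = y(te);
    for (int j = 0; j < A; ++j) {
      vec r2 = yte - pred.col(j);
      sse(j) += dot(r2, r2);
    }
    n_out += te.n_elem;
  }
  return Rcpp::List::create(Rcpp::Named("sse") = sse,
                            Rcpp::Named("n_heldout") = n_out);
}

// Per-sample held-out residual accumulation for MCCV outlier screening at a
// fixed component count. Returns, per sample: number of times held out, sum of
// signed residuals, sum of |residuals|, sum of squared residuals.
// [[Rcpp::export(name = ".cpp_mccv_residuals")]]
Rcpp::List cpp_mccv_residuals(const arma::mat& X, const arma::vec& y,
                              const arma::imat& calmat, int A, double tol) {
  int n = X.n_rows;
  int R = calmat.n_cols;
  vec cnt(n, fill::zeros), s1(n, fill::zeros), sabs(n, fill::zeros),
      s2(n, fill::zeros);
  for (int r = 0; r < R; ++r) {
    std::vector<char> in_cal(n, 0);
    for (unsigned int i = 0; i < calmat.n_rows; ++i)
      in_cal[calmat(i, r) - 1] = 1;
    uvec tr(calmat.n_rows), te(n - calmat.n_rows);
    int a = 0, b = 0;
    for (int i = 0; i < n; ++i) (in_cal[i] ? tr(a++) : te(b++)) = i;
    if (te.n_elem == 0) continue;
    mat pred = holdout_pred_curve(X.rows(tr), y(tr), X.rows(te), A, tol);
    vec res = y(te) - pred.col(A - 1);
    for (unsigned int i = 0; i < te.n_elem; ++i) {
      int s = te(i);
      cnt(s) += 1.0;
      s1(s) += res(i);
      sabs(s) += std::fabs(res(i));
      s2(s) += res(i) * res(i);
    }
  }
  return Rcpp::List::create(Rcpp::Named("count") = cnt,
                            Rcpp::Named("sum") = s1,
                            Rcpp::Named("sum_abs") = sabs,
                            Rcpp::Named("sum_sq") = s2);
}
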
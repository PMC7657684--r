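// NIPALS PLS1 and its leave-one-out cross-validation kernel.
// Hot loop of the synergy-interval search, hence compiled.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core NIPALS on already-centered data. Fills the regression-coefficient
// matrix B (p x ncomp): column a holds the coefficients of the a-component
// model in the original (centered) variable space. Returns the number of
// components actually extracted (< ncomp only if X is deflated to noise).
static int nipals_core(mat X, vec y, int ncomp, double tol, int maxit,
                       mat &B, mat &W, mat &P, mat &T, vec &q) {
  const uword p = X.n_cols;
  mat R(p, ncomp, fill::zeros);          // W (P'W)^{-1}, built incrementally
  vec b(p, fill::zeros);
  int done = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < 1e-14) break;               // no covariance left to model
    w /= nw;
    // iterative refinement (converges immediately for a single response,
    // kept in the general fixed-point form with an explicit tolerance)
    vec t = X * w;
    int it = 0;
    for (; it < maxit; ++it) {
      double tt = dot(t, t);
      if (tt < 1e-300) Rcpp::stop("NIPALS breakdown at component %d", a + 1);
      double c = dot(y, t) / tt;
      vec u = y * (1.0 / c);             // PLS1 surrogate for the Y-score
      vec w_new = X.t() * u;
      w_new /= norm(w_new);
      double delta = norm(w_new - w);
      w = w_new;
      t = X * w;
      if (delta < tol) break;
    }
    if (it >= maxit)
      Rcpp::stop("NIPALS did not converge for component %d", a + 1);
    double tt = dot(t, t);
    vec pl = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    X -= t * pl.t();
    y -= qa * t;
    // r_a = w_a - sum_{j<a} (p_j' w_a) r_j
    vec r = w;
    for (int j = 0; j < a; ++j) r -= dot(P.col(j), w) * R.col(j);
    R.col(a) = r;
    b += qa * r;
    B.col(a) = b;
    W.col(a) = w;
    P.col(a) = pl;
    T.col(a) = t;
    q(a) = qa;
    done = a + 1;
  }
  // pad: a k-component request on data supporting fewer keeps the last model
  for (int a = done; a < ncomp; ++a) B.col(a) = b;
  return done;
}

// [[Rcpp::export]]
Rcpp::List cpp_nipals_pls(const arma::mat &X, const arma::vec &y, int ncomp,
                          double tol, int maxit) {
  if (X.n_rows != y.n_elem) Rcpp::stop("X and y dimensions disagree");
  rowvec xm = mean(X, 0);
  double ym = mean(y);
  mat Xc = X.each_row() - xm;
  vec yc = y - ym;
  mat B(X.n_cols, ncomp, fill::zeros);
  mat W(X.n_cols, ncomp, fill::zeros);
  mat P(X.n_cols, ncomp, fill::zeros);
  mat T(X.n_rows, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros);
  int done = nipals_core(Xc, yc, ncomp, tol, maxit, B, W, P, T, q);
  return Rcpp::List::create(
      Rcpp::Named("coefficients") = B, Rcpp::Named("weights") = W,
      Rcpp::Named("loadings") = P, Rcpp::Named("scores") = T,
      Rcpp::Named("q") = q, Rcpp::Named("x_mean") = xm,
      Rcpp::Named("y_mean") = ym, Rcpp::Named("n_extracted") = done);
}

// Covariance-form PLS1: works on the centred Gram matrix A = X'X and
// covariance vector s = X'y instead of X itself. For a single response this
// produces exactly the NIPALS coefficient path (the weight fixed point
// converges in one step), at O(p^2) per component instead of O(n p).
// Fills B (p x ncomp) with the coefficient path on the centred scale.
static void pls1_gram(mat A, vec s, int ncomp, mat &B) {
  const uword p = A.n_rows;
  mat P(p, ncomp, fill::zeros), R(p, ncomp, fill::zeros);
  vec b(p, fill::zeros);
  int done = 0;
  for (int a = 0; a < ncomp; ++a) {
    double ns = norm(s);
    if (ns < 1e-14) break;
    vec w = s / ns;
    vec Aw = A * w;
    double tt = dot(w, Aw);
    if (tt < 1e-300) break;
    vec pl = Aw / tt;
    double ty = dot(w, s);          // t'y
    double qa = ty / tt;
    A -= tt * (pl * pl.t());
    s -= ty * pl;
    vec r = w;
    for (int j = 0; j < a; ++j) r -= dot(P.col(j), w) * R.col(j);
    P.col(a) = pl;
    R.col(a) = r;
    b += qa * r;
    B.col(a) = b;
    done = a + 1;
  }
  for (int a = done; a < ncomp; ++a) B.col(a) = b;
}

// Leave-one-out predictions for PLS models with 1..max_k components.
// Row i of the returned matrix is the prediction of sample i from the model
// fitted on all other samples. Uses the covariance (Gram) form with rank-one
// fold updates when p is comparable to n, and the X-space NIPALS otherwise;
// both yield the same PLS1 solution.
// [[Rcpp::export]]
arma::mat cpp_pls_loocv(const arma::mat &X, const arma::vec &y, int max_k,
                        double tol, int maxit) {
  const uword n = X.n_rows, p = X.n_cols;
  if (n < 3) Rcpp::stop("need at least 3 samples for leave-one-out");
  int kmax = std::min<int>(max_k, std::min<uword>(n - 2, p));
  mat pred(n, max_k, fill::zeros);
  if (p <= 2 * n) {
    // one-time cross products over the full data, downdated per fold
    mat U = X.t() * X;               // sum_j x_j x_j'
    vec v = X.t() * y;               // sum_j x_j y_j
    rowvec sx = sum(X, 0);
    double sy = accu(y);
    const double nn = double(n) - 1.0;
    mat B(p, kmax, fill::zeros);
    for (uword i = 0; i < n; ++i) {
      vec xi = X.row(i).t();
      vec m = (sx.t() - xi) / nn;
      double ym = (sy - y(i)) / nn;
      mat A = U - xi * xi.t() - nn * (m * m.t());
      vec s = v - xi * y(i) - nn * ym * m;
      B.zeros();
      pls1_gram(A, s, kmax, B);
      vec xc = xi - m;
      for (int k = 0; k < max_k; ++k)
        pred(i, k) = ym + dot(xc, B.col(std::min(k, kmax - 1)));
    }
  } else {
    mat Xi(n - 1, p);
    vec yi(n - 1);
    for (uword i = 0; i < n; ++i) {
      uword r = 0;
      for (uword j = 0; j < n; ++j) {
        if (j == i) continue;
        Xi.row(r) = X.row(j);
        yi(r) = y(j);
        ++r;
      }
      rowvec xm = mean(Xi, 0);
      double ym = mean(yi);
      mat Xc = Xi.each_row() - xm;
      vec yc = yi - ym;
      mat B(p, kmax, fill::zeros);
      mat W(p, kmax, fill::zeros), P(p, kmax, fill::zeros);
      mat T(n - 1, kmax, fill::zeros);
      vec q(kmax, fill::zeros);
      nipals_core(Xc, yc, kmax, tol, maxit, B, W, P, T, q);
      rowvec xc = X.row(i) - xm;
      for (int k = 0; k < max_k; ++k)
        pred(i, k) = ym + dot(xc, B.col(std::min(k, kmax - 1)));
    }
  }
  return pred;
}
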
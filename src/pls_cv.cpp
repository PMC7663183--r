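#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// NIPALS PLS1: train on (Xtr, ytr), predict Xval for every component count
// 1..ncomp. Columns of the returned matrix are predictions with k components.
static mat pls1_predict_path(const mat& Xtr, const vec& ytr, const mat& Xval,
                             int ncomp) {
  const int p = Xtr.n_cols;
  rowvec xm = mean(Xtr, 0);
  double ym = mean(ytr);
  mat X = Xtr;
  X.each_row() -= xm;
  vec y = ytr - ym;
  mat Xv = Xval;
  Xv.each_row() -= xm;

  mat W(p, ncomp, fill::zeros), P(p, ncomp, fill::zeros);
  vec q(ncomp, fill::zeros);
  int used = 0;
  for (int a = 0; a < ncomp; ++a) {
    vec w = X.t() * y;
    double nw = norm(w);
    if (nw < 1e-12) break;
    w /= nw;
    vec t = X * w;
    double tt = dot(t, t);
    if (tt < 1e-12) break;
    vec pl = X.t() * t / tt;
    double qa = dot(y, t) / tt;
    X -= t * pl.t();
    y -= qa * t;
    W.col(a) = w;
    P.col(a) = pl;
    q(a) = qa;
    ++used;
  }

  mat preds(Xval.n_rows, ncomp);
  preds.fill(ym);
  for (int k = 1; k <= used; ++k) {
    mat Wk = W.cols(0, k - 1);
    mat Pk = P.cols(0, k - 1);
    vec bk;
    bool ok = solve(bk, Pk.t() * Wk, q.subvec(0, k - 1));
    if (!ok) break;
    preds.col(k - 1) = Xv * (Wk * bk) + ym;
  }
  for (int k = used + 1; k <= ncomp; ++k) {
    preds.col(k - 1) = preds.col(std::max(used, 1) - 1);
  }
  return preds;
}

//' @name cpp_pls_cv_rmse
//' @title Cross-validated PLS1 RMSE per component count (internal)
//' @noRd
// [[Rcpp::export]]
arma::vec cpp_pls_cv_rmse(const arma::mat& X, const arma::vec& y,
                          const arma::ivec& fold, int max_comp) {
  const int n = X.n_rows;
  int ncomp = std::min<int>(max_comp, std::min<int>(X.n_cols, n - 2));
  if (ncomp < 1) ncomp = 1;
  vec sse(ncomp, fill::zeros);
  int nfold = fold.max();
  for (int f = 1; f <= nfold; ++f) {
    uvec val = find(fold == f);
    uvec trn = find(fold != f);
    if (val.n_elem == 0 || trn.n_elem < 3) continue;
    mat preds = pls1_predict_path(X.rows(trn), y(trn), X.rows(val), ncomp);
    for (int k = 0; k < ncomp; ++k) {
      vec r = y(val) - preds.col(k);
      sse(k) += dot(r, r);
    }
  }
  return sqrt(sse / n);
}
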
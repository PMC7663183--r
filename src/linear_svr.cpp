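#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Linear epsilon-insensitive SVR solved by dual coordinate descent
// (L1-loss dual, one box-constrained variable per sample; cf. Ho & Lin,
// "Large-scale linear support vector regression"). The bias is carried as
// an augmented unit feature, which regularises it weakly; on centred
// responses the optimal bias is near zero, so this matches the
// equality-constrained formulation closely. Deterministic: the in-sweep
// coordinate order comes from a fixed xorshift generator, so results are
// identical across platforms and calls.
//
// Dual: min_beta 1/2 b' Q b - y' b + eps * ||b||_1, beta_i in [-C, C],
// Q = X X' (with the bias column included), w = X' beta.
// XaT holds one SAMPLE per contiguous column ((p+1) x n), which keeps the
// inner coordinate updates cache-friendly.
static void solve_svr(const mat& XaT, const vec& yc, double cost,
                      double epsilon, double tol, int max_sweeps,
                      vec& w, int& sweeps_out, bool& converged) {
  const int n = XaT.n_cols;
  vec qii(n);
  for (int i = 0; i < n; ++i) qii(i) = dot(XaT.col(i), XaT.col(i));

  vec beta(n, fill::zeros);
  w.zeros(XaT.n_rows);
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned long long lcg = 88172645463325252ULL;
  auto next_u = [&lcg]() {
    lcg ^= lcg << 13; lcg ^= lcg >> 7; lcg ^= lcg << 17;
    return lcg;
  };
  int sweeps = 0;
  bool conv = false;
  for (; sweeps < max_sweeps; ++sweeps) {
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(next_u() % (i + 1));
      std::swap(order[i], order[j]);
    }
    double max_viol = 0.0;
    for (int k = 0; k < n; ++k) {
      int i = order[k];
      if (qii(i) <= 0) continue;
      double G = dot(w, XaT.col(i)) - yc(i);
      double Gp = G + epsilon, Gn = G - epsilon;
      double b0 = beta(i), bnew = b0, viol = 0.0;
      if (b0 > 0) {
        viol = std::fabs(Gp);
        bnew = b0 - Gp / qii(i);
        if (bnew < 0) bnew = 0;          // sign change handled next sweep
      } else if (b0 < 0) {
        viol = std::fabs(Gn);
        bnew = b0 - Gn / qii(i);
        if (bnew > 0) bnew = 0;
      } else {
        if (Gp < 0) { viol = -Gp; bnew = -Gp / qii(i); }
        else if (Gn > 0) { viol = Gn; bnew = -Gn / qii(i); }
      }
      if (bnew > cost) bnew = cost;
      if (bnew < -cost) bnew = -cost;
      double d = bnew - b0;
      if (d != 0.0) {
        beta(i) = bnew;
        w += d * XaT.col(i);
      }
      // at the box bound the one-sided pull does not block convergence
      if ((b0 >= cost && Gp < 0) || (b0 <= -cost && Gn > 0)) viol = 0.0;
      if (viol > max_viol) max_viol = viol;
    }
    if (max_viol < tol) { conv = true; ++sweeps; break; }
  }
  sweeps_out = sweeps;
  converged = conv;
}

// [[Rcpp::export]]
Rcpp::List cpp_linear_svr(const arma::mat& X, const arma::vec& y,
                          double cost, double epsilon,
                          double tol = 1e-6, int max_sweeps = 20000) {
  const int n = X.n_rows, p = X.n_cols;
  mat XaT(p + 1, n);
  if (p > 0) XaT.rows(0, p - 1) = X.t();
  XaT.row(p).ones();
  double ym = mean(y);
  vec yc = y - ym;
  vec w;
  int sweeps; bool conv;
  solve_svr(XaT, yc, cost, epsilon, tol, max_sweeps, w, sweeps, conv);
  return Rcpp::List::create(
      Rcpp::Named("weights") = vec(w.subvec(0, p - 1)),
      Rcpp::Named("intercept") = w(p) + ym,
      Rcpp::Named("sweeps") = sweeps,
      Rcpp::Named("converged") = conv);
}

// Repeated k-fold CV for one (C, epsilon) pair: fold is an n x n_repeats
// matrix of fold labels 1..k. Returns per-repeat RMSE and R2 of the pooled
// held-out predictions.
// [[Rcpp::export]]
Rcpp::List cpp_svr_cv(const arma::mat& X, const arma::vec& y,
                      const arma::imat& fold, double cost, double epsilon,
                      double tol = 1e-4, int max_sweeps = 200) {
  const int n = X.n_rows, p = X.n_cols, nrep = fold.n_cols;
  vec rmse(nrep), r2(nrep);
  double ytot_mean = 0.0;
  for (int r = 0; r < nrep; ++r) {
    vec pred(n, fill::zeros);
    int kmax = fold.col(r).max();
    for (int f = 1; f <= kmax; ++f) {
      uvec val = find(fold.col(r) == f);
      uvec trn = find(fold.col(r) != f);
      if (val.n_elem == 0 || trn.n_elem < 2) continue;
      mat XaT(p + 1, trn.n_elem);
      if (p > 0) XaT.rows(0, p - 1) = X.rows(trn).t();
      XaT.row(p).ones();
      vec ytr = y(trn);
      double ym = mean(ytr);
      vec w;
      int sw; bool cv_;
      solve_svr(XaT, ytr - ym, cost, epsilon, tol, max_sweeps, w, sw, cv_);
      vec pv = X.rows(val) * w.subvec(0, p - 1) + w(p) + ym;
      pred(val) = pv;
    }
    vec res = y - pred;
    rmse(r) = std::sqrt(dot(res, res) / n);
    double sstot = dot(y - mean(y), y - mean(y));
    r2(r) = 1.0 - dot(res, res) / sstot;
    (void)ytot_mean;
  }
  return Rcpp::List::create(Rcpp::Named("rmse") = rmse,
                            Rcpp::Named("r2") = r2);
}
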
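// NIPALS partial least squares core.
//
// X and Y must arrive column-centred; centring vectors are managed on the
// R side so that train/test application is explicit there.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Core NIPALS on centred blocks; fills W/P/C and returns the number of
// latent variables actually extracted.
static int nipals_core(mat X, mat Y, int n_lv, double tol, int max_iter,
                       mat& W, mat& P, mat& C) {
  const uword n = X.n_rows, p = X.n_cols, q = Y.n_cols;
  W.set_size(p, n_lv); P.set_size(p, n_lv); C.set_size(q, n_lv);
  int kept = 0;
  for (int a = 0; a < n_lv; ++a) {
    uword j = index_max(sum(square(Y), 0));
    vec u = Y.col(j);
    if (norm(u) < 1e-14) break;
    vec w(p), t(n), c(q), t_old(n, fill::zeros);
    for (int it = 0; it < max_iter; ++it) {
      w = X.t() * u;
      double nw = norm(w);
      if (nw < 1e-14) break;
      w /= nw;
      t = X * w;
      double tt = dot(t, t);
      if (tt < 1e-14) break;
      c = Y.t() * t / tt;
      double nc = norm(c);
      if (nc < 1e-14) break;
      u = Y * c / dot(c, c);
      if (norm(t - t_old) / std::max(norm(t), 1e-300) < tol) break;
      t_old = t;
    }
    double tt = dot(t, t);
    if (tt < 1e-14 || !t.is_finite()) break;
    vec pl = X.t() * t / tt;
    X -= t * pl.t();
    Y -= t * c.t();
    W.col(a) = w; P.col(a) = pl; C.col(a) = c;
    kept = a + 1;
  }
  return kept;
}

// Leave-one-out PLS-DA correctness matrix: row i, column a is 1 when the
// held-out sample i is correctly classified by an a-LV model fitted on the
// remaining rows (blocks re-centred per fold), NA-coded as -1 when a LVs
// were not reachable in that fold.
// [[Rcpp::export]]
arma::imat cpp_plsda_loo(const arma::mat& X, const arma::mat& Y,
                         const arma::uvec& truth, int max_lv,
                         double tol, int max_iter) {
  const uword n = X.n_rows;
  imat correct(n, max_lv);
  correct.fill(-1);
  mat W, P, C;
  for (uword i = 0; i < n; ++i) {
    mat Xt = X; Xt.shed_row(i);
    mat Yt = Y; Yt.shed_row(i);
    rowvec xc = mean(Xt, 0), yc = mean(Yt, 0);
    Xt.each_row() -= xc;
    Yt.each_row() -= yc;
    int kept = nipals_core(Xt, Yt, max_lv, tol, max_iter, W, P, C);
    if (kept < 1) continue;
    mat Wk = W.cols(0, kept - 1), Pk = P.cols(0, kept - 1),
        Ck = C.cols(0, kept - 1);
    mat R;
    if (!solve(R, (Pk.t() * Wk).t(), Wk.t()))   // R = Wk (Pk'Wk)^{-1}
      continue;
    rowvec t0 = (X.row(i) - xc) * R.t();
    rowvec pred = yc;
    for (int a = 0; a < kept; ++a) {
      pred += t0(a) * Ck.col(a).t();
      correct(i, a) = (pred.index_max() == truth(i)) ? 1 : 0;
    }
  }
  return correct;
}

// [[Rcpp::export]]
Rcpp::List cpp_nipals(arma::mat X, arma::mat Y, int n_lv,
                      double tol, int max_iter) {
  const uword n = X.n_rows, p = X.n_cols, q = Y.n_cols;
  mat W(p, n_lv, fill::zeros);   // X weights
  mat P(p, n_lv, fill::zeros);   // X loadings
  mat C(q, n_lv, fill::zeros);   // Y loadings (weights on the dummy block)
  mat T(n, n_lv, fill::zeros);   // X scores
  vec xres(n_lv, fill::zeros);   // residual X sum of squares after each LV
  ivec iters(n_lv, fill::zeros);

  int kept = 0;
  for (int a = 0; a < n_lv; ++a) {
    // start u from the Y column with the largest variance
    uword j = index_max(sum(square(Y), 0));
    vec u = Y.col(j);
    if (norm(u) < 1e-14) break;   // Y exhausted

    vec w(p), t(n), c(q), t_old(n, fill::zeros);
    int it = 0;
    for (; it < max_iter; ++it) {
      w = X.t() * u;
      double nw = norm(w);
      if (nw < 1e-14) break;
      w /= nw;
      t = X * w;
      double tt = dot(t, t);
      if (tt < 1e-14) break;
      c = Y.t() * t / tt;
      double nc = norm(c);
      if (nc < 1e-14) break;
      u = Y * c / dot(c, c);
      if (norm(t - t_old) / std::max(norm(t), 1e-300) < tol) { ++it; break; }
      t_old = t;
    }
    double tt = dot(t, t);
    if (tt < 1e-14 || !t.is_finite()) break;
    vec pl = X.t() * t / tt;
    X -= t * pl.t();
    Y -= t * c.t();

    W.col(a) = w; P.col(a) = pl; C.col(a) = c; T.col(a) = t;
    xres(a) = accu(square(X));
    iters(a) = it;
    kept = a + 1;
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W.cols(0, std::max(kept - 1, 0)),
    Rcpp::Named("P") = P.cols(0, std::max(kept - 1, 0)),
    Rcpp::Named("C") = C.cols(0, std::max(kept - 1, 0)),
    Rcpp::Named("T") = T.cols(0, std::max(kept - 1, 0)),
    Rcpp::Named("x_residual_ss") = xres.subvec(0, std::max(kept - 1, 0)),
    Rcpp::Named("iterations") = iters.subvec(0, std::max(kept - 1, 0)),
    Rcpp::Named("n_lv") = kept);
}
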
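// Correlation optimised warping: segment-wise dynamic programming over
// sample boundary placements, maximizing the summed Pearson correlation
// between reference segments and linearly interpolated sample segments.
//
// Tie-break among equal-score paths: minimize cumulative |stretch|
// (absolute deviation of each sample segment length from its reference
// segment length), so the minimal-deformation alignment is returned.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const double SCORE_EPS = 1e-12;

// Pearson correlation of ref[u0..u1] with samp interpolated from
// [x0, x1] onto u1-u0+1 equally spaced positions; 0 if either side is
// (numerically) constant.
static double seg_corr(const vec& ref, const vec& samp,
                       int u0, int u1, int x0, int x1) {
  const int m = u1 - u0 + 1;           // points in the reference segment
  vec a(m), b(m);
  const double step = (double)(x1 - x0) / (double)(u1 - u0);
  for (int k = 0; k < m; ++k) {
    a(k) = ref(u0 + k);
    double pos = x0 + step * k;
    int lo = (int)std::floor(pos);
    if (lo >= x1) { b(k) = samp(x1); continue; }
    double fr = pos - lo;
    b(k) = (1.0 - fr) * samp(lo) + fr * samp(lo + 1);
  }
  double ma = mean(a), mb = mean(b);
  a -= ma; b -= mb;
  double sa = norm(a), sb = norm(b);
  if (sa < 1e-12 || sb < 1e-12) return 0.0;
  return dot(a, b) / (sa * sb);
}

// [[Rcpp::export]]
Rcpp::List cpp_cow(const arma::vec& ref, const arma::vec& samp,
                   const arma::ivec& bounds, int slack) {
  const int N  = bounds.n_elem - 1;    // number of segments
  const int LS = samp.n_elem;

  // per-segment reference lengths and admissible sample lengths
  ivec dref(N), dmin(N), dmax(N);
  for (int i = 0; i < N; ++i) {
    dref(i) = bounds(i + 1) - bounds(i);
    dmin(i) = std::max(1, dref(i) - slack);
    dmax(i) = dref(i) + slack;
  }

  // feasible sample-position window for each boundary
  ivec lo(N + 1), hi(N + 1);
  lo(0) = hi(0) = 0;
  for (int i = 1; i <= N; ++i) {
    lo(i) = lo(i - 1) + dmin(i - 1);
    hi(i) = hi(i - 1) + dmax(i - 1);
  }
  ivec lo2(N + 1), hi2(N + 1);
  lo2(N) = hi2(N) = LS - 1;
  for (int i = N - 1; i >= 0; --i) {
    lo2(i) = lo2(i + 1) - dmax(i);
    hi2(i) = hi2(i + 1) - dmin(i);
  }
  for (int i = 0; i <= N; ++i) {
    lo(i) = std::max(lo(i), lo2(i));
    hi(i) = std::min(hi(i), hi2(i));
    if (lo(i) > hi(i))
      Rcpp::stop("infeasible warp: slack too small for the length difference");
  }

  // forward DP over boundary positions
  std::vector<vec>  score(N + 1);
  std::vector<vec>  stretch(N + 1);
  std::vector<ivec> pred(N + 1);
  for (int i = 0; i <= N; ++i) {
    int w = hi(i) - lo(i) + 1;
    score[i]   = vec(w);  score[i].fill(-datum::inf);
    stretch[i] = vec(w);  stretch[i].fill(datum::inf);
    pred[i]    = ivec(w); pred[i].fill(-1);
  }
  score[0](0) = 0.0;
  stretch[0](0) = 0.0;

  for (int i = 0; i < N; ++i) {
    for (int x = lo(i); x <= hi(i); ++x) {
      double s0 = score[i](x - lo(i));
      if (!std::isfinite(s0)) continue;
      double st0 = stretch[i](x - lo(i));
      for (int d = dmin(i); d <= dmax(i); ++d) {
        int x2 = x + d;
        if (x2 < lo(i + 1) || x2 > hi(i + 1)) continue;
        double r  = seg_corr(ref, samp, bounds(i), bounds(i + 1), x, x2);
        double sc = s0 + r;
        double st = st0 + std::abs((double)(d - dref(i)));
        int k = x2 - lo(i + 1);
        if (sc > score[i + 1](k) + SCORE_EPS ||
            (sc > score[i + 1](k) - SCORE_EPS && st < stretch[i + 1](k))) {
          score[i + 1](k) = sc;
          stretch[i + 1](k) = st;
          pred[i + 1](k) = x;
        }
      }
    }
  }

  // backtrack (terminal boundary is pinned at LS-1)
  ivec xb(N + 1);
  xb(N) = LS - 1;
  for (int i = N; i > 0; --i)
    xb(i - 1) = pred[i](xb(i) - lo(i));

  vec segscore(N);
  for (int i = 0; i < N; ++i)
    segscore(i) = seg_corr(ref, samp, bounds(i), bounds(i + 1),
                           xb(i), xb(i + 1));

  // warped trace on the reference grid
  vec warped(bounds(N) - bounds(0) + 1);
  for (int i = 0; i < N; ++i) {
    int m = dref(i);
    double step = (double)(xb(i + 1) - xb(i)) / (double)m;
    for (int k = 0; k <= m; ++k) {
      double pos = xb(i) + step * k;
      int l = (int)std::floor(pos);
      double fr = pos - l;
      double v = (l >= xb(i + 1)) ? samp(xb(i + 1))
                                  : (1.0 - fr) * samp(l) + fr * samp(l + 1);
      warped(bounds(i) + k) = v;
    }
  }

  return Rcpp::List::create(
    Rcpp::Named("sample_bounds") = xb,
    Rcpp::Named("segment_scores") = segscore,
    Rcpp::Named("total_score") = accu(segscore),
    Rcpp::Named("total_stretch") = stretch[N](xb(N) - lo(N)),
    Rcpp::Named("warped") = warped);
}
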
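// Hartigan & Hartigan's dip statistic for unimodality.
//
// Computes dip(F_n) = min over unimodal cdfs G of sup |F_n - G|, via the
// iterative greatest-convex-minorant / least-concave-majorant scheme on a
// shrinking modal interval. Distances are accumulated in ECDF-step units
// (1/n) and halved at the end; the minimal attainable value is 1/(2n).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".dip_stat_cpp")]]
double dip_stat_cpp(NumericVector xs) {
  const int n = xs.size();
  if (n < 1) stop("empty sample");
  for (int k = 1; k < n; ++k)
    if (xs[k] < xs[k - 1]) stop("x must be sorted");
  if (n == 1) return 0.0;
  if (xs[n - 1] == xs[0]) return 0.0;  // all values identical: no dip

  const double *x = REAL(xs);
  std::vector<int> mn(n), mj(n), gcm(n + 1), lcm(n + 1);

  // Convex-minorant predecessor pointers over the full sample: mn[j] is the
  // previous touch point of the lower convex hull of (x[i], i).
  mn[0] = 0;
  for (int j = 1; j < n; ++j) {
    mn[j] = j - 1;
    for (;;) {
      int mnj = mn[j], mnmnj = mn[mnj];
      if (mnj == 0 ||
          (x[j] - x[mnj]) * (mnj - mnmnj) < (x[mnj] - x[mnmnj]) * (j - mnj))
        break;
      mn[j] = mnmnj;
    }
  }
  // Concave-majorant successor pointers.
  mj[n - 1] = n - 1;
  for (int k = n - 2; k >= 0; --k) {
    mj[k] = k + 1;
    for (;;) {
      int mjk = mj[k], mjmjk = mj[mjk];
      if (mjk == n - 1 ||
          (x[k] - x[mjk]) * (mjk - mjmjk) < (x[mjk] - x[mjmjk]) * (k - mjk))
        break;
      mj[k] = mjmjk;
    }
  }

  int low = 0, high = n - 1;
  double dip = 1.0;  // in 1/n units; final value is dip/(2n) >= 1/(2n)

  for (;;) {
    // GCM touch points from high down to low.
    int l_gcm;
    {
      int i = 0;
      gcm[0] = high;
      while (gcm[i] > low) { gcm[i + 1] = mn[gcm[i]]; ++i; }
      l_gcm = i;  // gcm[l_gcm] == low
    }
    // LCM touch points from low up to high.
    int l_lcm;
    {
      int i = 0;
      lcm[0] = low;
      while (lcm[i] < high) { lcm[i + 1] = mj[lcm[i]]; ++i; }
      l_lcm = i;  // lcm[l_lcm] == high
    }

    int ig = l_gcm, ih = l_lcm;
    double d = 0.0;
    if (l_gcm != 1 || l_lcm != 1) {
      // Largest distance between the two curves, sweeping both touch-point
      // lists across [low, high]; ix counts down the gcm list, iv up the lcm.
      int ix = l_gcm - 1, iv = 1;
      for (;;) {
        int gcmix = gcm[ix], lcmiv = lcm[iv];
        double dx;
        if (gcmix > lcmiv) {
          // next change point comes from the LCM: deviation of the lcm touch
          // point above the gcm chord through (gcm[ix+1], gcm[ix])
          int gcmi1 = gcm[ix + 1];
          dx = (lcmiv - gcmi1 + 1) -
               (x[lcmiv] - x[gcmi1]) * (gcmix - gcmi1) / (x[gcmix] - x[gcmi1]);
          ++iv;
          if (dx >= d) { d = dx; ig = ix + 1; ih = iv - 1; }
        } else {
          // next change point comes from the GCM: deviation of the gcm touch
          // point below the lcm chord through (lcm[iv-1], lcm[iv])
          int lcmiv1 = lcm[iv - 1];
          dx = (x[gcmix] - x[lcmiv1]) * (lcmiv - lcmiv1) /
                   (x[lcmiv] - x[lcmiv1]) -
               (gcmix - lcmiv1 - 1);
          --ix;
          if (dx > d) { d = dx; ig = ix + 1; ih = iv; }
        }
        if (ix < 0) ix = 0;
        if (iv > l_lcm) iv = l_lcm;
        if (gcm[ix] == lcm[iv]) break;
      }
    } else {
      d = 1.0;
    }
    if (d < dip) break;

    // Maximal deviation of the ECDF above the convex minorant between
    // successive gcm touch points outside the current modal interval.
    double dip_l = 0.0;
    for (int j = ig; j < l_gcm; ++j) {
      double max_t = 1.0;
      int jb = gcm[j + 1], je = gcm[j];
      if (je - jb > 1 && x[je] != x[jb]) {
        double C = (je - jb) / (x[je] - x[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (jj - jb + 1) - (x[jj] - x[jb]) * C;
          if (max_t < t) max_t = t;
        }
      }
      if (dip_l < max_t) dip_l = max_t;
    }
    // Maximal deviation of the ECDF below the concave majorant.
    double dip_u = 0.0;
    for (int j = ih; j < l_lcm; ++j) {
      double max_t = 1.0;
      int jb = lcm[j], je = lcm[j + 1];
      if (je - jb > 1 && x[je] != x[jb]) {
        double C = (je - jb) / (x[je] - x[jb]);
        for (int jj = jb; jj <= je; ++jj) {
          double t = (x[jj] - x[jb]) * C - (jj - jb - 1);
          if (max_t < t) max_t = t;
        }
      }
      if (dip_u < max_t) dip_u = max_t;
    }

    double dipnew = (dip_l > dip_u) ? dip_l : dip_u;
    if (dip < dipnew) dip = dipnew;

    if (low == gcm[ig] && high == lcm[ih]) break;  // modal interval stable
    low = gcm[ig];
    high = lcm[ih];
  }

  return dip / (2.0 * n);
}
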
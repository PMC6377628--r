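#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Half-amplitude level assignment with hysteresis.
// x is the current in units of the unitary amplitude. The running level L
// changes only when the signal moves more than `threshold` level units away
// from L, and then jumps to the nearest non-negative integer level.
// [[Rcpp::export]]
IntegerVector hysteresis_levels(NumericVector x, double threshold) {
  int n = x.size();
  IntegerVector lev(n);
  long L = std::lround(std::max(x[0], 0.0));
  lev[0] = (int)L;
  for (int i = 1; i < n; i++) {
    double d = x[i] - (double)L;
    if (d > threshold || d < -threshold) {
      long k = std::lround(x[i]);
      if (k < 0) k = 0;
      L = k;
    }
    lev[i] = (int)L;
  }
  return lev;
}

// Dead-time filtering of an event list: events shorter than dead_time are
// absorbed, shortest first, into the longer neighboring event (ties toward
// the preceding event); adjacent events left at equal levels are combined.
// [[Rcpp::export]]
List merge_dead_time(IntegerVector levels, NumericVector durations,
                     double dead_time) {
  std::vector<int> lv(levels.begin(), levels.end());
  std::vector<double> du(durations.begin(), durations.end());
  const double eps = 1e-12;
  while (lv.size() > 1) {
    // shortest event below the dead time
    int m = -1;
    double best = dead_time - eps;
    for (size_t i = 0; i < du.size(); i++) {
      if (du[i] < best) { best = du[i]; m = (int)i; }
    }
    if (m < 0) break;
    int nb;
    if (m == 0) nb = 1;
    else if (m == (int)lv.size() - 1) nb = m - 1;
    else nb = (du[m + 1] > du[m - 1]) ? m + 1 : m - 1;  // tie -> preceding
    du[nb] += du[m];
    lv.erase(lv.begin() + m);
    du.erase(du.begin() + m);
    // combine equal adjacent levels near the removal point
    for (int j = std::max(m - 2, 0); j + 1 < (int)lv.size() && j <= m + 1; ) {
      if (lv[j] == lv[j + 1]) {
        du[j] += du[j + 1];
        lv.erase(lv.begin() + j + 1);
        du.erase(du.begin() + j + 1);
      } else j++;
    }
  }
  return List::create(_["levels"] = wrap(lv), _["durations"] = wrap(du));
}
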
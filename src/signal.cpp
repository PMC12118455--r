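#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Changepoint segmentation: Welch t-statistic between adjacent windows of
// size w; boundaries at local maxima of |t| exceeding `tthresh`, accepted
// greedily left-to-right with a minimum event length.
// Returns 0-based boundary positions (a boundary at i splits samples
// [.., i) and [i, ..)); the implicit boundaries 0 and n are not returned.
// [[Rcpp::export(name = ".segment_boundaries_cpp")]]
IntegerVector segment_boundaries_cpp(NumericVector x, int w, double tthresh,
                                     int min_len) {
  const int n = x.size();
  if (n < 2 * w) stop("signal too short for window size");
  std::vector<double> cs(n + 1, 0.0), cs2(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    cs[i + 1] = cs[i] + x[i];
    cs2[i + 1] = cs2[i] + x[i] * x[i];
  }
  const double eps = 1e-12;
  std::vector<double> tstat(n + 1, 0.0); // tstat[i]: boundary before sample i
  for (int i = w; i + w <= n; ++i) {
    double sl = cs[i] - cs[i - w], sl2 = cs2[i] - cs2[i - w];
    double sr = cs[i + w] - cs[i], sr2 = cs2[i + w] - cs2[i];
    double ml = sl / w, mr = sr / w;
    double vl = std::max(0.0, (sl2 - sl * ml) / std::max(1, w - 1));
    double vr = std::max(0.0, (sr2 - sr * mr) / std::max(1, w - 1));
    double se = std::sqrt(vl / w + vr / w + eps);
    tstat[i] = std::fabs(ml - mr) / se;
  }
  std::vector<int> out;
  int last = 0;
  for (int i = w; i + w <= n; ++i) {
    double t = tstat[i];
    if (t < tthresh) continue;
    // local maximum, keeping the leftmost sample of a tied plateau
    if (!(t > tstat[i - 1] && t >= tstat[i + 1])) continue;
    if (i - last < min_len) continue; // enforce min event length
    if (n - i < min_len) continue;    // trailing event would be too short
    out.push_back(i);
    last = i;
  }
  return wrap(out);
}

// Banded dynamic-programming alignment of segmented events to expected
// per-base levels. Each event is assigned to exactly one base; assignments
// are monotone non-decreasing in base index; bases receiving no event
// ("skips") incur `skip_cost` each. Cost of assigning event i to base j is
// |event_mean[i] - expected[j]|. Cost-equal choices resolve toward the
// diagonal of the event/base rectangle.
// Returns list(base_of_event = 1-based base per event, cost).
// [[Rcpp::export(name = ".align_banded_cpp")]]
List align_banded_cpp(NumericVector event_means, NumericVector expected,
                      int band, double skip_cost) {
  const int ne = event_means.size(), nb = expected.size();
  if (ne == 0 || nb == 0) stop("empty alignment input");
  const double INF = std::numeric_limits<double>::infinity();
  const double TOL = 1e-12;
  std::vector<int> lof(ne + 1), hif(ne + 1), diag(ne + 1);
  for (int i = 1; i <= ne; ++i) {
    diag[i] = (int)std::llround((double)i * nb / ne);
    int lo = diag[i] - band, hi = diag[i] + band;
    lof[i] = lo < 1 ? 1 : lo;
    hif[i] = hi > nb ? nb : hi;
  }
  const int width = 2 * band + 1;
  std::vector<double> Dprev(nb + 2, INF), Dcur(nb + 2, INF);
  std::vector<int> prevj((size_t)ne * width, -1);
  for (int j = lof[1]; j <= hif[1]; ++j) {
    Dprev[j] = std::fabs(event_means[0] - expected[j - 1]) + skip_cost * (j - 1);
  }
  for (int i = 2; i <= ne; ++i) {
    std::fill(Dcur.begin(), Dcur.end(), INF);
    const int lo = lof[i], hi = hif[i];
    const int plo = lof[i - 1], phi = hif[i - 1];
    // running minimum over j' <= j-1 of D[i-1][j'] - skip_cost * j'
    double runmin = INF;
    int runarg = -1;
    int jp = plo;
    for (int j = lo; j <= hi; ++j) {
      while (jp <= phi && jp < j) {
        double v = Dprev[jp] - skip_cost * jp;
        // keep the largest j' on ties: fewest skipped bases, nearest diagonal
        if (v < runmin - TOL || (v <= runmin + TOL && jp > runarg)) {
          runmin = v;
          runarg = jp;
        }
        ++jp;
      }
      double best = INF;
      int arg = -1;
      if (j >= plo && j <= phi && std::isfinite(Dprev[j])) { // stay on base j
        best = Dprev[j];
        arg = j;
      }
      if (runarg >= 0) { // advance from j' < j, skipping j-j'-1 bases
        double adv = runmin + skip_cost * (j - 1);
        if (adv < best - TOL ||
            (adv <= best + TOL && arg >= 0 &&
             std::abs(runarg - diag[i - 1]) < std::abs(arg - diag[i - 1]))) {
          best = adv;
          arg = runarg;
        }
      }
      if (arg < 0) continue;
      Dcur[j] = best + std::fabs(event_means[i - 1] - expected[j - 1]);
      prevj[(size_t)(i - 1) * width + (j - lo)] = arg;
    }
    std::swap(Dprev, Dcur);
  }
  // terminal: bases after the last event's base are skipped
  double best = INF;
  int bestj = -1;
  for (int j = lof[ne]; j <= hif[ne]; ++j) {
    if (!std::isfinite(Dprev[j])) continue;
    double tot = Dprev[j] + skip_cost * (nb - j);
    if (tot < best - TOL || (tot <= best + TOL && j > bestj)) {
      best = tot;
      bestj = j;
    }
  }
  if (bestj < 0) stop("alignment band too narrow: no feasible path");
  IntegerVector base_of_event(ne);
  int j = bestj;
  for (int i = ne; i >= 1; --i) {
    base_of_event[i - 1] = j;
    if (i > 1) j = prevj[(size_t)(i - 1) * width + (j - lof[i])];
  }
  return List::create(_["base_of_event"] = base_of_event, _["cost"] = best);
}
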
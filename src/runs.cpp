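// Hot-path helpers shared by the event classifiers: run-length encoding of
// per-frame predicates with merge/min-duration post-processing, the 3x3
// skeleton minimum distance, and the truncated centered rolling mean.
#include <Rcpp.h>
using namespace Rcpp;

// pred: 1 = true, 0 = false, 2 = gap (NA; never merged across).
// Post-processing order: (1) maximal true runs, (2) runs shorter than
// min_frames dropped, (3) surviving runs whose separation is at most
// merge_gap frames with no tracking gap in between are merged. Returns
// half-open 0-based [start, end) intervals.
// [[Rcpp::export]]
IntegerMatrix runs_encode_cpp(IntegerVector pred, int min_frames,
                              int merge_gap) {
  int n = pred.size();
  std::vector<int> starts, ends;
  int i = 0;
  while (i < n) {
    if (pred[i] == 1) {
      int s = i;
      while (i < n && pred[i] == 1) ++i;
      if (i - s >= min_frames) { starts.push_back(s); ends.push_back(i); }
    } else ++i;
  }
  // merge surviving runs across short clean separations
  std::vector<int> ms, me;
  for (size_t k = 0; k < starts.size(); ++k) {
    if (!ms.empty() && starts[k] - me.back() <= merge_gap) {
      bool clean = true;
      for (int j = me.back(); j < starts[k]; ++j)
        if (pred[j] == 2) { clean = false; break; }
      if (clean) { me.back() = ends[k]; continue; }
    }
    ms.push_back(starts[k]);
    me.push_back(ends[k]);
  }
  IntegerMatrix out(ms.size(), 2);
  for (size_t k = 0; k < ms.size(); ++k) {
    out(k, 0) = ms[k];
    out(k, 1) = me[k];
  }
  return out;
}

// Minimum over the 9 point-pair distances of two 3-point skeletons.
// Returns dmin and the 1-based column-major pair index (focal point fastest:
// nose, center, tail) x (partner nose, center, tail).
// [[Rcpp::export]]
List skeleton_min_cpp(NumericMatrix a, NumericMatrix b) {
  // a, b: n x 6 matrices (nx, ny, cx, cy, tx, ty)
  int n = a.nrow();
  NumericVector dmin(n);
  IntegerVector arg(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bk = NA_INTEGER;
    bool na = false;
    int k = 0;
    for (int j = 0; j < 3; ++j) {
      double bx = b(i, 2 * j), by = b(i, 2 * j + 1);
      for (int q = 0; q < 3; ++q) {
        ++k;
        double dx = a(i, 2 * q) - bx, dy = a(i, 2 * q + 1) - by;
        double dd = std::sqrt(dx * dx + dy * dy);
        if (ISNAN(dd)) { na = true; break; }
        if (dd < best) { best = dd; bk = k; }
      }
      if (na) break;
    }
    if (na) { dmin[i] = NA_REAL; arg[i] = NA_INTEGER; }
    else { dmin[i] = best; arg[i] = bk; }
  }
  return List::create(_["dmin"] = dmin, _["argmin"] = arg);
}

// Centered rolling mean, window truncated at the vector ends; half-widths
// floor((w-1)/2) left and floor(w/2) right.
// [[Rcpp::export]]
NumericVector roll_mean_cpp(NumericVector x, int w) {
  int n = x.size();
  NumericVector out(n);
  if (w <= 1 || n == 1) return clone(x);
  int hl = (w - 1) / 2, hr = w / 2;
  for (int i = 0; i < n; ++i) {
    int lo = i - hl < 0 ? 0 : i - hl;
    int hi = i + hr >= n ? n - 1 : i + hr;
    double s = 0.0;
    for (int j = lo; j <= hi; ++j) s += x[j];
    out[i] = s / (hi - lo + 1);
  }
  return out;
}
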
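// Stateful frame scan for approach events. The per-frame contract:
// an approach by the focal starts at the first frame with
//   dist < radius  AND  dist strictly decreasing  AND
//   focal speed > partner speed  AND  not in contact,
// and ends at contact onset (subtype with_contact), on zone exit, when the
// distance has stopped decreasing for max(1, merge_gap) consecutive frames
// (end = first non-decreasing frame), or at a tracking gap (subtype
// without_contact in all non-contact cases). Events shorter than
// min_frames are dropped. Frames are 0-based, intervals half-open.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix scan_approaches_cpp(NumericVector dist, LogicalVector in_contact,
                                  NumericVector spd_f, NumericVector spd_p,
                                  double radius, int merge_gap,
                                  int min_frames) {
  int n = dist.size();
  int g = merge_gap < 1 ? 1 : merge_gap;
  std::vector<int> starts, ends, with;
  bool open = false;
  int start = 0, nondec = 0;

  for (int i = 1; i < n; ++i) {
    bool valid = !NumericVector::is_na(dist[i]) &&
                 !NumericVector::is_na(dist[i - 1]) &&
                 !NumericVector::is_na(spd_f[i]) &&
                 !NumericVector::is_na(spd_p[i]) &&
                 !LogicalVector::is_na(in_contact[i]);
    int emit_end = -1, emit_with = 0;
    if (open) {
      if (!valid) {
        emit_end = i;
      } else if (in_contact[i]) {
        emit_end = i; emit_with = 1;
      } else if (dist[i] >= radius) {
        emit_end = i;
      } else if (dist[i] < dist[i - 1]) {
        nondec = 0;
      } else {
        ++nondec;
        if (nondec >= g) emit_end = i - nondec + 1;
      }
      if (emit_end >= 0) {
        if (emit_end - start >= min_frames) {
          starts.push_back(start); ends.push_back(emit_end);
          with.push_back(emit_with);
        }
        open = false;
      }
    }
    if (!open && valid && dist[i] < radius && dist[i] < dist[i - 1] &&
        spd_f[i] > spd_p[i] && !in_contact[i]) {
      open = true; start = i; nondec = 0;
    }
  }
  if (open && n - start >= min_frames) {
    starts.push_back(start); ends.push_back(n); with.push_back(0);
  }

  IntegerMatrix out(starts.size(), 3);
  for (size_t k = 0; k < starts.size(); ++k) {
    out(k, 0) = starts[k]; out(k, 1) = ends[k]; out(k, 2) = with[k];
  }
  colnames(out) = CharacterVector::create("start", "end", "with_contact");
  return out;
}
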
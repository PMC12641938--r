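#include <Rcpp.h>
using namespace Rcpp;

// Maximum pairwise Euclidean separation of a 2-D point set (degrees on the
// flat scene plane; small-angle regime, all reported amplitudes < 1 deg).
// [[Rcpp::export(name = ".cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericVector x, NumericVector y) {
  R_xlen_t n = x.size();
  double m2 = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    for (R_xlen_t j = i + 1; j < n; ++j) {
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 > m2) m2 = d2;
    }
  }
  return std::sqrt(m2);
}

// Greedy left-to-right I-DT windowing. The stream is first split into
// segments at temporal gaps exceeding `gap_break` seconds (samples removed
// by confidence filtering, blinks, dropouts). Within a segment, a window
// grows from the left while its maximum pairwise dispersion stays within
// `max_disp` and its time span within `max_dur`; it is emitted as a
// fixation when the span reaches `min_dur`. Dwells longer than `max_dur`
// therefore split into consecutive capped fixations. Earliest-start
// windows win ties by construction.
// Returns a 2-column integer matrix of 1-based inclusive (start, end)
// sample indices.
// [[Rcpp::export(name = ".cpp_idt_windows")]]
IntegerMatrix cpp_idt_windows(NumericVector t, NumericVector x,
                              NumericVector y, double max_disp,
                              double min_dur, double max_dur,
                              double gap_break) {
  R_xlen_t n = t.size();
  std::vector<int> ws, we;
  const double eps = 1e-9;
  R_xlen_t seg_start = 0;
  for (R_xlen_t seg_end = 0; seg_end < n; ++seg_end) {
    bool boundary = (seg_end == n - 1) ||
                    (t[seg_end + 1] - t[seg_end] > gap_break + eps);
    if (!boundary) continue;
    R_xlen_t i = seg_start;
    while (i <= seg_end) {
      R_xlen_t j = i;
      double maxd2 = 0.0;
      while (j < seg_end) {
        R_xlen_t cand = j + 1;
        if (t[cand] - t[i] > max_dur + eps) break;
        double newmax = maxd2;
        for (R_xlen_t k = i; k <= j; ++k) {
          double dx = x[cand] - x[k], dy = y[cand] - y[k];
          double d2 = dx * dx + dy * dy;
          if (d2 > newmax) newmax = d2;
        }
        if (std::sqrt(newmax) > max_disp + eps) break;
        maxd2 = newmax;
        j = cand;
      }
      if (t[j] - t[i] >= min_dur - eps) {
        ws.push_back(static_cast<int>(i) + 1);
        we.push_back(static_cast<int>(j) + 1);
        i = j + 1;
      } else {
        i += 1;
      }
    }
    seg_start = seg_end + 1;
  }
  IntegerMatrix out(static_cast<int>(ws.size()), 2);
  for (size_t k = 0; k < ws.size(); ++k) {
    out(k, 0) = ws[k];
    out(k, 1) = we[k];
  }
  return out;
}
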
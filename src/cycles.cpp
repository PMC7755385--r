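#include <Rcpp.h>
using namespace Rcpp;

// Per-pixel cycle decomposition of tubulin intensity traces.
//
// For each trace (row of `traces`, one value per frame):
//   1. centred moving-average smoothing (window truncated at the ends);
//   2. pixels whose dynamic range is below `min_range` are marked invalid;
//   3. mitotic episodes = maximal runs of the globally min-max-normalised
//      trace below 0.5, at least `min_mitotic_frames` long;
//   4. each episode defines one cycle whose window runs from the end of the
//      previous episode to the start of the next; the window is min-max
//      normalised and the entry time is the first downward crossing of
//      `theta`, the exit time the first upward crossing of `theta` after
//      entry, both with linear sub-frame interpolation.
//
// Times are reported in minutes: t = t0 + frame_index * dt (0-based).
// [[Rcpp::export]]
List decompose_cycles_cpp(NumericMatrix traces, double dt, double t0,
                          double theta, int smooth_window, double min_range,
                          int min_mitotic_frames, int max_cycles) {
  const int npx = traces.nrow(), nf = traces.ncol();
  NumericMatrix entry(npx, max_cycles), exitt(npx, max_cycles);
  std::fill(entry.begin(), entry.end(), NA_REAL);
  std::fill(exitt.begin(), exitt.end(), NA_REAL);
  IntegerVector ncyc(npx), ncomplete(npx);
  LogicalVector valid(npx);
  std::vector<double> y(nf), z(nf);
  const int hw = smooth_window / 2;

  for (int p = 0; p < npx; ++p) {
    // smoothing
    for (int i = 0; i < nf; ++i) {
      int lo = std::max(0, i - hw), hi = std::min(nf - 1, i + hw);
      double s = 0.0;
      for (int j = lo; j <= hi; ++j) s += traces(p, j);
      y[i] = s / (hi - lo + 1);
    }
    double mn = y[0], mx = y[0];
    for (int i = 1; i < nf; ++i) { mn = std::min(mn, y[i]); mx = std::max(mx, y[i]); }
    if (mx - mn < min_range) { valid[p] = false; continue; }
    valid[p] = true;
    for (int i = 0; i < nf; ++i) z[i] = (y[i] - mn) / (mx - mn);

    // mitotic episodes: runs of z < 0.5
    std::vector<int> ep_start, ep_end;
    int i = 0;
    while (i < nf) {
      if (z[i] < 0.5) {
        int j = i;
        while (j + 1 < nf && z[j + 1] < 0.5) ++j;
        if (j - i + 1 >= min_mitotic_frames) { ep_start.push_back(i); ep_end.push_back(j); }
        i = j + 1;
      } else ++i;
    }

    int nc = 0, ncomp = 0;
    for (size_t e = 0; e < ep_start.size() && nc < max_cycles; ++e) {
      int ws = (e == 0) ? 0 : ep_end[e - 1] + 1;
      int we = (e + 1 < ep_start.size()) ? ep_start[e + 1] - 1 : nf - 1;
      // window min-max normalisation
      double wmn = y[ws], wmx = y[ws];
      for (int k = ws + 1; k <= we; ++k) { wmn = std::min(wmn, y[k]); wmx = std::max(wmx, y[k]); }
      if (wmx - wmn < min_range) continue;
      double t_entry = NA_REAL, t_exit = NA_REAL;
      int k_entry = -1;
      for (int k = ws; k < we; ++k) {
        double a = (y[k] - wmn) / (wmx - wmn), b = (y[k + 1] - wmn) / (wmx - wmn);
        if (a >= theta && b < theta) {
          t_entry = t0 + dt * (k + (a - theta) / (a - b));
          k_entry = k;
          break;
        }
      }
      if (k_entry >= 0) {
        for (int k = k_entry + 1; k < we; ++k) {
          double a = (y[k] - wmn) / (wmx - wmn), b = (y[k + 1] - wmn) / (wmx - wmn);
          if (a < theta && b >= theta) {
            t_exit = t0 + dt * (k + (theta - a) / (b - a));
            break;
          }
        }
      }
      if (!ISNA(t_entry)) {
        entry(p, nc) = t_entry;
        exitt(p, nc) = t_exit;
        if (!ISNA(t_exit)) ++ncomp;
        ++nc;
      }
    }
    ncyc[p] = nc;
    ncomplete[p] = ncomp;
  }
  return List::create(_["entry"] = entry, _["exit"] = exitt,
                      _["n_cycles"] = ncyc, _["n_complete"] = ncomplete,
                      _["valid"] = valid);
}
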
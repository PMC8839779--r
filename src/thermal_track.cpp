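#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// Stack layout: numeric array with dim = c(H, W, T), column-major,
// 0-based (row, col) indexing on the R side converted here as needed.

static inline double px(const NumericVector &stack, int H, int W,
                        int r, int c, int t) {
  return stack[r + H * (c + W * t)];
}

// Integer-displacement block matching between consecutive frames.
// For each ROI centre, the patch (2*patch_half+1)^2 around the previous
// centre in frame t-1 is compared (SSD) against candidate displacements
// within `radius` in frame t; the minimising displacement updates the
// centre.  Ties prefer the smallest displacement magnitude, then
// row-major candidate order, making tracks deterministic.
// Returns per-ROI tracks (T x 2, 0-based row/col) and the first frame
// index (1-based, 0 = never) at which the patch left the image.
// [[Rcpp::export]]
List cpp_track_centres(NumericVector stack, IntegerVector dims,
                       IntegerMatrix centres0, int patch_half, int radius) {
  const int H = dims[0], W = dims[1], T = dims[2];
  const int n = centres0.nrow();
  List tracks(n);
  IntegerVector lost(n);
  for (int k = 0; k < n; ++k) {
    IntegerMatrix tr(T, 2);
    int r0 = centres0(k, 0), c0 = centres0(k, 1);
    tr(0, 0) = r0; tr(0, 1) = c0;
    int lost_at = 0;
    if (r0 - patch_half < 0 || r0 + patch_half >= H ||
        c0 - patch_half < 0 || c0 + patch_half >= W)
      lost_at = 1;
    for (int t = 1; t < T; ++t) {
      if (lost_at) { tr(t, 0) = r0; tr(t, 1) = c0; continue; }
      double best = R_PosInf;
      int best_dr = 0, best_dc = 0, best_mag = INT_MAX;
      for (int dr = -radius; dr <= radius; ++dr) {
        for (int dc = -radius; dc <= radius; ++dc) {
          int rc = r0 + dr, cc = c0 + dc;
          if (rc - patch_half < 0 || rc + patch_half >= H ||
              cc - patch_half < 0 || cc + patch_half >= W) continue;
          double ssd = 0.0;
          for (int i = -patch_half; i <= patch_half; ++i)
            for (int j = -patch_half; j <= patch_half; ++j) {
              double d = px(stack, H, W, r0 + i, c0 + j, t - 1) -
                         px(stack, H, W, rc + i, cc + j, t);
              ssd += d * d;
            }
          int mag = dr * dr + dc * dc;
          if (ssd < best - 1e-12 ||
              (std::abs(ssd - best) <= 1e-12 && mag < best_mag)) {
            best = ssd; best_dr = dr; best_dc = dc; best_mag = mag;
          }
        }
      }
      if (!R_finite(best)) { lost_at = t + 1; tr(t,0)=r0; tr(t,1)=c0; continue; }
      r0 += best_dr; c0 += best_dc;
      if (r0 - patch_half < 0 || r0 + patch_half >= H ||
          c0 - patch_half < 0 || c0 + patch_half >= W)
        lost_at = t + 1;
      tr(t, 0) = r0; tr(t, 1) = c0;
    }
    tracks[k] = tr;
    lost[k] = lost_at;
  }
  return List::create(_["tracks"] = tracks, _["lost"] = lost);
}

// Median ROI temperature per frame.  The ROI is the set of pixel offsets
// (dr, dc) re-centred on the per-frame tracked centre; offsets falling
// outside the frame are dropped.  `flag` marks frames where no ROI pixel
// lies in the open face-temperature interval (t_lo, t_hi).
// [[Rcpp::export]]
List cpp_roi_median_series(NumericVector stack, IntegerVector dims,
                           IntegerMatrix track, IntegerVector dr,
                           IntegerVector dc, double t_lo, double t_hi) {
  const int H = dims[0], W = dims[1], T = dims[2];
  const int m = dr.size();
  NumericVector out(T);
  LogicalVector flag(T);
  std::vector<double> vals;
  vals.reserve(m);
  for (int t = 0; t < T; ++t) {
    vals.clear();
    int in_face = 0;
    int r0 = track(t, 0), c0 = track(t, 1);
    for (int i = 0; i < m; ++i) {
      int r = r0 + dr[i], c = c0 + dc[i];
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      double v = px(stack, H, W, r, c, t);
      vals.push_back(v);
      if (v > t_lo && v < t_hi) ++in_face;
    }
    if (vals.empty()) { out[t] = NA_REAL; flag[t] = true; continue; }
    flag[t] = (in_face == 0);
    size_t n = vals.size(), mid = n / 2;
    std::nth_element(vals.begin(), vals.begin() + mid, vals.end());
    double med = vals[mid];
    if (n % 2 == 0) {
      std::nth_element(vals.begin(), vals.begin() + mid - 1,
                       vals.begin() + mid);
      med = 0.5 * (med + vals[mid - 1]);
    }
    out[t] = med;
  }
  return List::create(_["values"] = out, _["flag"] = flag);
}
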
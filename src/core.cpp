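#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Pixel coordinates are 0-based in this file; the R wrappers convert.
// x = column, y = row throughout.

// The circular template of radius r is the integer annulus
// {(dx, dy): (r - 0.5)^2 <= dx^2 + dy^2 < (r + 0.5)^2}. All quantities are
// exactly representable, so the pixel set is identical across compilers
// and across the R oracle (no transcendental knife-edges).
static void ring_offsets(int r, std::vector<int>& dx, std::vector<int>& dy) {
  dx.clear(); dy.clear();
  double lo = (r - 0.5) * (r - 0.5), hi = (r + 0.5) * (r + 0.5);
  for (int y = -r - 1; y <= r + 1; ++y) {
    for (int x = -r - 1; x <= r + 1; ++x) {
      double d2 = (double)x * x + (double)y * y;
      if (d2 >= lo && d2 < hi) { dx.push_back(x); dy.push_back(y); }
    }
  }
}

// [[Rcpp::export]]
double cpp_ring_mean(NumericMatrix img, int cx, int cy, int r) {
  std::vector<int> dx, dy;
  ring_offsets(r, dx, dy);
  const int nr = img.nrow(), nc = img.ncol();
  double s = 0.0; int cnt = 0;
  for (size_t k = 0; k < dx.size(); ++k) {
    int px = cx + dx[k], py = cy + dy[k];
    if (px >= 0 && px < nc && py >= 0 && py < nr) { s += img(py, px); ++cnt; }
  }
  return cnt > 0 ? s / cnt : NA_REAL;
}

// Circular edge detection: maximize mean(ring r+2) - mean(ring r) over a
// center grid (step grid_step) and integer radii in [rmin, rmax]. Centers are
// restricted so the outer ring fits inside the frame. Ties: smaller radius,
// then smaller y, then smaller x (guaranteed by scan order with strict >).
// [[Rcpp::export]]
List cpp_ced_search(NumericMatrix img, int rmin, int rmax, int grid_step,
                    int cx0, int cy0, int cx1, int cy1) {
  const int nr = img.nrow(), nc = img.ncol();
  const double* p = REAL(img);
  double best = R_NegInf; int bx = -1, by = -1, br = -1;
  std::vector<int> dx, dy;
  std::vector<int> lin_i, lin_o;   // linear (column-major) sample offsets
  for (int r = rmin; r <= rmax; ++r) {
    ring_offsets(r, dx, dy);
    lin_i.resize(dx.size());
    for (size_t k = 0; k < dx.size(); ++k) lin_i[k] = dy[k] + dx[k] * nr;
    double ni = (double)lin_i.size();
    ring_offsets(r + 2, dx, dy);
    lin_o.resize(dx.size());
    for (size_t k = 0; k < dx.size(); ++k) lin_o[k] = dy[k] + dx[k] * nr;
    double no = (double)lin_o.size();
    // the center bounds keep both annuli fully inside: no bounds checks
    int lo_x = std::max(cx0, r + 2), hi_x = std::min(cx1, nc - 1 - (r + 2));
    int lo_y = std::max(cy0, r + 2), hi_y = std::min(cy1, nr - 1 - (r + 2));
    for (int cx = lo_x; cx <= hi_x; cx += grid_step) {
      for (int cy = lo_y; cy <= hi_y; cy += grid_step) {
        const double* base = p + cy + (R_xlen_t)cx * nr;
        double so = 0.0, si = 0.0;
        for (size_t k = 0; k < lin_o.size(); ++k) so += base[lin_o[k]];
        for (size_t k = 0; k < lin_i.size(); ++k) si += base[lin_i[k]];
        double sc = so / no - si / ni;
        if (sc > best + 1e-12 ||
            (std::abs(sc - best) <= 1e-12 &&
             (r < br || (r == br && (cy < by || (cy == by && cx < bx)))))) {
          best = sc; bx = cx; by = cy; br = r;
        }
      }
    }
  }
  return List::create(_["x"] = bx, _["y"] = by, _["r"] = br, _["score"] = best);
}

// SAD block matching along rows. Disparity d at (r, c) minimizes
// SAD(ref block at (r, c), tgt block at (r, c - d)), d in [-range, range].
// Ties resolved toward smallest |d|, then smallest d (scan 0,-1,+1,-2,...).
// Border pixels whose reference block does not fit are NA; candidate d whose
// target block does not fit is skipped.
// [[Rcpp::export]]
NumericMatrix cpp_sad_disparity(NumericMatrix ref, NumericMatrix tgt,
                                int block, int range) {
  const int nr = ref.nrow(), nc = ref.ncol(), h = block / 2;
  NumericMatrix out(nr, nc);
  std::fill(out.begin(), out.end(), NA_REAL);
  std::vector<int> ds;
  ds.push_back(0);
  for (int m = 1; m <= range; ++m) { ds.push_back(-m); ds.push_back(m); }
  for (int r = h; r < nr - h; ++r) {
    for (int c = h; c < nc - h; ++c) {
      double bestCost = R_PosInf; int bestD = NA_INTEGER;
      for (size_t q = 0; q < ds.size(); ++q) {
        int d = ds[q], cc = c - d;
        if (cc - h < 0 || cc + h >= nc) continue;
        double cost = 0.0;
        for (int i = -h; i <= h; ++i)
          for (int j = -h; j <= h; ++j)
            cost += std::abs(ref(r + i, c + j) - tgt(r + i, cc + j));
        if (cost < bestCost - 1e-9) { bestCost = cost; bestD = d; }
      }
      if (bestD != NA_INTEGER) out(r, c) = bestD;
    }
  }
  return out;
}

// 2-D correlation with replicate (clamp-to-edge) border handling.
// [[Rcpp::export]]
NumericMatrix cpp_conv2_replicate(NumericMatrix img, NumericMatrix kern) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kr = kern.nrow(), kc = kern.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      double s = 0.0;
      for (int i = 0; i < kr; ++i) {
        int rr = r + i - hr;
        rr = rr < 0 ? 0 : (rr >= nr ? nr - 1 : rr);
        for (int j = 0; j < kc; ++j) {
          int cc = c + j - hc;
          cc = cc < 0 ? 0 : (cc >= nc ? nc - 1 : cc);
          s += kern(i, j) * img(rr, cc);
        }
      }
      out(r, c) = s;
    }
  }
  return out;
}

// 8-connected component labelling of a logical mask (flood fill, iterative).
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < nc; ++c0) {
    for (int r0 = 0; r0 < nr; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * nr);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int r = idx % nr, c = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            int rr = r + dr, cc = c + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
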
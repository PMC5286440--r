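#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Images are R matrices indexed [row, col] = [y + 1, x + 1]; all point
// coordinates crossing this interface are 0-based with x = column, y = row.

static inline double tps_U(double d2) {
  // U(r) = r^2 log(r^2), expressed in the squared distance; U(0) = 0
  return d2 > 0.0 ? d2 * std::log(d2) : 0.0;
}

// Evaluate a fitted TPS at a set of points.
// anchors: n x 2 (x, y); coefx/coefy: length n + 3, ordered (w_1..w_n, a1, ax, ay).
// [[Rcpp::export]]
NumericMatrix cpp_tps_eval(NumericMatrix anchors, NumericVector coefx,
                           NumericVector coefy, NumericMatrix pts) {
  const int n = anchors.nrow(), m = pts.nrow();
  NumericMatrix out(m, 2);
  for (int i = 0; i < m; ++i) {
    const double x = pts(i, 0), y = pts(i, 1);
    double sx = coefx[n] + coefx[n + 1] * x + coefx[n + 2] * y;
    double sy = coefy[n] + coefy[n + 1] * x + coefy[n + 2] * y;
    for (int j = 0; j < n; ++j) {
      const double dx = x - anchors(j, 0), dy = y - anchors(j, 1);
      const double u = tps_U(dx * dx + dy * dy);
      sx += coefx[j] * u;
      sy += coefy[j] * u;
    }
    out(i, 0) = sx;
    out(i, 1) = sy;
  }
  return out;
}

static inline double bilinear(const NumericMatrix& img, double x, double y) {
  const int H = img.nrow(), W = img.ncol();
  // tolerate solver-level roundoff at the domain boundary
  const double eps = 1e-6;
  if (x < -eps || y < -eps || x > W - 1.0 + eps || y > H - 1.0 + eps)
    return 0.0;
  if (x < 0.0) x = 0.0;
  if (y < 0.0) y = 0.0;
  if (x > W - 1.0) x = W - 1.0;
  if (y > H - 1.0) y = H - 1.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 > W - 2) x0 = W - 2;
  if (y0 > H - 2) y0 = H - 2;
  if (x0 < 0) x0 = 0;
  if (y0 < 0) y0 = 0;
  const double fx = x - x0, fy = y - y0;
  const double v00 = img(y0, x0), v01 = img(y0, x0 + 1);
  const double v10 = img(y0 + 1, x0), v11 = img(y0 + 1, x0 + 1);
  return (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11);
}

// Warp an image through a backward TPS map (output pixel -> source position).
// [[Rcpp::export]]
NumericMatrix cpp_tps_warp(NumericMatrix src, NumericMatrix anchors,
                           NumericVector coefx, NumericVector coefy,
                           int outH, int outW) {
  const int n = anchors.nrow();
  NumericMatrix out(outH, outW);
  for (int yy = 0; yy < outH; ++yy) {
    for (int xx = 0; xx < outW; ++xx) {
      double sx = coefx[n] + coefx[n + 1] * xx + coefx[n + 2] * yy;
      double sy = coefy[n] + coefy[n + 1] * xx + coefy[n + 2] * yy;
      for (int j = 0; j < n; ++j) {
        const double dx = xx - anchors(j, 0), dy = yy - anchors(j, 1);
        const double u = tps_U(dx * dx + dy * dy);
        sx += coefx[j] * u;
        sy += coefy[j] * u;
      }
      out(yy, xx) = bilinear(src, sx, sy);
    }
  }
  return out;
}

static double mi_from_joint(const std::vector<double>& joint,
                            int bins, double total) {
  if (total <= 0.0) return 0.0;
  std::vector<double> pa(bins, 0.0), pb(bins, 0.0);
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      pa[i] += joint[i + bins * j];
      pb[j] += joint[i + bins * j];
    }
  double mi = 0.0;
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      const double p = joint[i + bins * j] / total;
      if (p > 0.0) mi += p * std::log(p * total * total /
                                      (pa[i] * pb[j]));
    }
  return mi;
}

static inline int mi_bin(double v, int bins) {
  if (v < 0.0) v = 0.0;
  if (v > 1.0) v = 1.0;
  int b = (int)(v * bins);
  return b >= bins ? bins - 1 : b;
}

// Mutual information (nats) from the joint histogram of two equal-shape
// images with intensities clamped to [0, 1].
// [[Rcpp::export]]
double cpp_mi(NumericMatrix a, NumericMatrix b, int bins) {
  const int N = a.nrow() * a.ncol();
  std::vector<double> joint(bins * bins, 0.0);
  for (int k = 0; k < N; ++k)
    joint[mi_bin(a[k], bins) + bins * mi_bin(b[k], bins)] += 1.0;
  return mi_from_joint(joint, bins, (double)N);
}

// Warp src through a backward TPS and return MI against tgt in one pass
// (no intermediate image allocation; used by the SOM winner search).
// stride > 1 scores on a subsampled pixel grid.
// [[Rcpp::export]]
double cpp_tps_warp_mi(NumericMatrix src, NumericMatrix tgt,
                       NumericMatrix anchors, NumericVector coefx,
                       NumericVector coefy, int bins, int stride = 1) {
  const int n = anchors.nrow(), H = tgt.nrow(), W = tgt.ncol();
  std::vector<double> joint(bins * bins, 0.0);
  double total = 0.0;
  for (int yy = 0; yy < H; yy += stride) {
    for (int xx = 0; xx < W; xx += stride) {
      double sx = coefx[n] + coefx[n + 1] * xx + coefx[n + 2] * yy;
      double sy = coefy[n] + coefy[n + 1] * xx + coefy[n + 2] * yy;
      for (int j = 0; j < n; ++j) {
        const double dx = xx - anchors(j, 0), dy = yy - anchors(j, 1);
        const double u = tps_U(dx * dx + dy * dy);
        sx += coefx[j] * u;
        sy += coefy[j] * u;
      }
      const double v = bilinear(src, sx, sy);
      joint[mi_bin(v, bins) + bins * mi_bin(tgt(yy, xx), bins)] += 1.0;
      total += 1.0;
    }
  }
  return mi_from_joint(joint, bins, total);
}

// Zhang-Suen thinning with a cleanup pass that deletes 8-simple pixels
// sitting in fully-set 2x2 blocks, so the result is strictly 1-px thin.
static inline int getpx(const IntegerMatrix& m, int y, int x) {
  if (y < 0 || x < 0 || y >= m.nrow() || x >= m.ncol()) return 0;
  return m(y, x) != 0 ? 1 : 0;
}

static bool zs_pass(IntegerMatrix& img, int step) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<std::pair<int, int> > kill;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!getpx(img, y, x)) continue;
      const int p2 = getpx(img, y - 1, x),     p3 = getpx(img, y - 1, x + 1);
      const int p4 = getpx(img, y, x + 1),     p5 = getpx(img, y + 1, x + 1);
      const int p6 = getpx(img, y + 1, x),     p7 = getpx(img, y + 1, x - 1);
      const int p8 = getpx(img, y, x - 1),     p9 = getpx(img, y - 1, x - 1);
      const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
      if (B < 2 || B > 6) continue;
      int A = 0;
      const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
      for (int k = 0; k < 8; ++k) if (seq[k] == 0 && seq[k + 1] == 1) ++A;
      if (A != 1) continue;
      if (step == 0) {
        if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
      } else {
        if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
      }
      kill.push_back(std::make_pair(y, x));
    }
  }
  for (size_t k = 0; k < kill.size(); ++k) img(kill[k].first, kill[k].second) = 0;
  return !kill.empty();
}

static bool is_simple(const IntegerMatrix& img, int y, int x) {
  // 8-simple: exactly one 0->1 transition around the pixel
  const int p[9] = {getpx(img, y - 1, x),     getpx(img, y - 1, x + 1),
                    getpx(img, y, x + 1),     getpx(img, y + 1, x + 1),
                    getpx(img, y + 1, x),     getpx(img, y + 1, x - 1),
                    getpx(img, y, x - 1),     getpx(img, y - 1, x - 1),
                    getpx(img, y - 1, x)};
  int A = 0, B = 0;
  for (int k = 0; k < 8; ++k) {
    B += p[k];
    if (p[k] == 0 && p[k + 1] == 1) ++A;
  }
  return A == 1 && B >= 2;
}

// [[Rcpp::export]]
IntegerMatrix cpp_thin(IntegerMatrix mask) {
  IntegerMatrix img = clone(mask);
  const int H = img.nrow(), W = img.ncol();
  bool changed = true;
  while (changed) {
    changed = zs_pass(img, 0);
    changed = zs_pass(img, 1) || changed;
  }
  // remove surviving fully-set 2x2 blocks
  bool again = true;
  while (again) {
    again = false;
    for (int y = 0; y + 1 < H; ++y)
      for (int x = 0; x + 1 < W; ++x)
        if (img(y, x) && img(y, x + 1) && img(y + 1, x) && img(y + 1, x + 1)) {
          const int ys[4] = {y, y, y + 1, y + 1};
          const int xs[4] = {x, x + 1, x, x + 1};
          for (int k = 0; k < 4; ++k)
            if (is_simple(img, ys[k], xs[k])) {
              img(ys[k], xs[k]) = 0;
              again = true;
              break;
            }
        }
  }
  return img;
}

static inline double circ_diff(double a, double b) {
  double d = std::fabs(a - b);
  const double two_pi = 2.0 * M_PI;
  while (d > two_pi) d -= two_pi;
  return d > M_PI ? two_pi - d : d;
}

// Relaxation matching: for each source point, scan every candidate center
// within `radius` of the same coordinates in the target and return the
// candidate minimizing the circular SAD of gradient directions over a
// W x W window. Zero-magnitude pixels (valid == 0) in either window are
// skipped. Windows must lie fully inside the image.
// angS/angT: gradient angle maps; valS/valT: 0/1 validity; xs/ys 0-based.
// Returns m x 4: (x_t, y_t, cost, second-peak cost), where the second
// peak is the best SAD among candidates more than 2 px from the winner
// (distinctiveness reference); costs are R_PosInf when nothing
// comparable.
// [[Rcpp::export]]
NumericMatrix cpp_relax_search(NumericMatrix angS, IntegerMatrix valS,
                               NumericMatrix angT, IntegerMatrix valT,
                               IntegerVector xs, IntegerVector ys,
                               int W, int radius) {
  const int H = angS.nrow(), Wd = angS.ncol();
  const int hw = W / 2, m = xs.size();
  const int side = 2 * radius + 1;
  std::vector<double> sads(side * side);
  NumericMatrix out(m, 4);
  for (int i = 0; i < m; ++i) {
    const int x0 = xs[i], y0 = ys[i];
    double best = R_PosInf;
    int bx = x0, by = y0, bdx = 0, bdy = 0;
    double bestd2 = R_PosInf;
    std::fill(sads.begin(), sads.end(), R_PosInf);
    for (int dy = -radius; dy <= radius; ++dy) {
      const int cy = y0 + dy;
      if (cy - hw < 0 || cy + hw >= H) continue;
      for (int dx = -radius; dx <= radius; ++dx) {
        const int cx = x0 + dx;
        if (cx - hw < 0 || cx + hw >= Wd) continue;
        double sad = 0.0;
        int nval = 0;
        for (int wy = -hw; wy <= hw; ++wy)
          for (int wx = -hw; wx <= hw; ++wx) {
            if (!valS(y0 + wy, x0 + wx) || !valT(cy + wy, cx + wx)) continue;
            sad += circ_diff(angS(y0 + wy, x0 + wx), angT(cy + wy, cx + wx));
            ++nval;
          }
        if (nval == 0) continue;
        sads[(dy + radius) * side + (dx + radius)] = sad;
        const double d2 = (double)dx * dx + (double)dy * dy;
        if (sad < best || (sad == best && d2 < bestd2)) {
          best = sad;
          bx = cx;
          by = cy;
          bdx = dx;
          bdy = dy;
          bestd2 = d2;
        }
      }
    }
    double second = R_PosInf;
    double subx = 0.0, suby = 0.0;
    if (R_FINITE(best)) {
      for (int dy = -radius; dy <= radius; ++dy)
        for (int dx = -radius; dx <= radius; ++dx) {
          const int ddx = dx - bdx, ddy = dy - bdy;
          if (ddx * ddx + ddy * ddy <= 4) continue;  // within 2 px of winner
          const double s = sads[(dy + radius) * side + (dx + radius)];
          if (s < second) second = s;
        }
      // parabolic subpixel refinement of the SAD minimum; a perfect
      // (zero-cost) match is already exact and is left untouched
      if (best > 0.0 && bdx > -radius && bdx < radius) {
        const double l = sads[(bdy + radius) * side + (bdx - 1 + radius)];
        const double r = sads[(bdy + radius) * side + (bdx + 1 + radius)];
        const double den = l - 2.0 * best + r;
        if (R_FINITE(l) && R_FINITE(r) && den > 0.0)
          subx = std::max(-0.5, std::min(0.5, 0.5 * (l - r) / den));
      }
      if (best > 0.0 && bdy > -radius && bdy < radius) {
        const double u = sads[(bdy - 1 + radius) * side + (bdx + radius)];
        const double d = sads[(bdy + 1 + radius) * side + (bdx + radius)];
        const double den = u - 2.0 * best + d;
        if (R_FINITE(u) && R_FINITE(d) && den > 0.0)
          suby = std::max(-0.5, std::min(0.5, 0.5 * (u - d) / den));
      }
    }
    out(i, 0) = bx + subx;
    out(i, 1) = by + suby;
    out(i, 2) = best;
    out(i, 3) = second;
  }
  return out;
}
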
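// Per-pixel hot loops of the counting pipeline: connected-component
// labelling, median filtering, Canny edge detection and the two Hough
// circle variants.  All image matrices are R orientation (row, col),
// 1-based coordinates at the R interface.

#include <Rcpp.h>
#include <algorithm>
#include <climits>
#include <cmath>
#include <vector>

using namespace Rcpp;

// reflect-101 border index (0-based): edge pixel not duplicated
static inline int reflect101(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * (n - 1);
  i %= period;
  if (i < 0) i += period;
  if (i >= n) i = period - i;
  return i;
}

// half-up rounding to [0, 255] integers
// [[Rcpp::export]]
IntegerMatrix cpp_quantize8(NumericMatrix x) {
  const R_xlen_t n = x.size();
  IntegerMatrix out(x.nrow(), x.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = std::floor(x[i] + 0.5);
    out[i] = (int)(v < 0 ? 0 : (v > 255 ? 255 : v));
  }
  return out;
}

// BT.601 luma of an 8-bit RGB image, rounded half-up
// [[Rcpp::export]]
IntegerMatrix cpp_luma(IntegerMatrix r, IntegerMatrix g, IntegerMatrix b) {
  const R_xlen_t n = r.size();
  IntegerMatrix out(r.nrow(), r.ncol());
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = std::floor(0.299 * r[i] + 0.587 * g[i] + 0.114 * b[i] + 0.5);
    out[i] = (int)(v < 0 ? 0 : (v > 255 ? 255 : v));
  }
  return out;
}

// vignetted bright disk on a dark surround: the synthetic background.
// Intensity base_in * (1 - strength*(1 - cos(pi/2 * rho/R))) inside the
// field of view, base_out outside, 1 px anti-aliased rim.
// [[Rcpp::export]]
NumericMatrix cpp_render_background(int h, int w, double cy, double cx,
                                    double R, double strength,
                                    double base_in, double base_out) {
  NumericMatrix out(h, w);
  for (int x = 0; x < w; ++x) {
    const double dx2 = (x + 1 - cx) * (x + 1 - cx);
    for (int y = 0; y < h; ++y) {
      const double rho = std::sqrt((y + 1 - cy) * (y + 1 - cy) + dx2);
      double frac = rho / R;
      if (frac > 1) frac = 1;
      const double bg = base_in * (1 - strength * (1 - std::cos(M_PI_2 * frac)));
      double a = R + 0.5 - rho;
      a = a < 0 ? 0 : (a > 1 ? 1 : a);
      out(y, x) = base_out * (1 - a) + bg * a;
    }
  }
  return out;
}

// Largest 4-connected component of a binary image.
// Returns list(mask, size, boundary) where boundary holds the 1-based
// (row, col) coordinates of component pixels with a 4-neighbor outside.
// [[Rcpp::export]]
List cpp_largest_component4(LogicalMatrix bw) {
  const int h = bw.nrow(), w = bw.ncol();
  std::vector<int> label((size_t)h * w, 0);
  int best_label = 0, best_size = 0, cur = 0;
  std::vector<int> stack;
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      const size_t idx = (size_t)x * h + y;
      if (!bw(y, x) || label[idx]) continue;
      ++cur;
      int size = 0;
      stack.clear();
      stack.push_back((int)idx);
      label[idx] = cur;
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        ++size;
        const int py = p % h, px = p / h;
        const int ny[4] = {py - 1, py + 1, py, py};
        const int nx[4] = {px, px, px - 1, px + 1};
        for (int k = 0; k < 4; ++k) {
          if (ny[k] < 0 || ny[k] >= h || nx[k] < 0 || nx[k] >= w) continue;
          const size_t q = (size_t)nx[k] * h + ny[k];
          if (bw(ny[k], nx[k]) && !label[q]) {
            label[q] = cur;
            stack.push_back((int)q);
          }
        }
      }
      if (size > best_size) { best_size = size; best_label = cur; }
    }
  }
  LogicalMatrix mask(h, w);
  std::vector<int> by, bx;
  if (best_label > 0) {
    for (size_t i = 0; i < (size_t)h * w; ++i)
      if (label[i] == best_label) mask[i] = true;
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        if (!mask(y, x)) continue;
        const bool edge =
          y == 0 || y == h - 1 || x == 0 || x == w - 1 ||
          !mask(y - 1, x) || !mask(y + 1, x) ||
          !mask(y, x - 1) || !mask(y, x + 1);
        if (edge) { by.push_back(y + 1); bx.push_back(x + 1); }
      }
  }
  IntegerMatrix boundary((int)by.size(), 2);
  for (size_t i = 0; i < by.size(); ++i) {
    boundary(i, 0) = by[i];
    boundary(i, 1) = bx[i];
  }
  return List::create(_["mask"] = mask, _["size"] = best_size,
                      _["boundary"] = boundary);
}

// Median filter with square window and reflect-101 borders.
// [[Rcpp::export]]
IntegerMatrix cpp_median_filter(IntegerMatrix img, int win) {
  const int h = img.nrow(), w = img.ncol(), half = win / 2;
  IntegerMatrix out(h, w);
  std::vector<int> buf((size_t)win * win);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      int k = 0;
      for (int dx = -half; dx <= half; ++dx) {
        const int xx = reflect101(x + dx, w);
        for (int dy = -half; dy <= half; ++dy)
          buf[k++] = img(reflect101(y + dy, h), xx);
      }
      std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
      out(y, x) = buf[k / 2];
    }
  }
  return out;
}

// Canny edge detector: Sobel gradients (reflect-101), quantized
// non-maximum suppression, double threshold with 8-connected hysteresis.
// Thresholds apply to the unnormalized Sobel L2 magnitude.
// Returns list(edges, gx, gy, mag).
// [[Rcpp::export]]
List cpp_canny(IntegerMatrix img, double high, double low) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix gx(h, w), gy(h, w), mag(h, w);
  for (int x = 0; x < w; ++x) {
    const int xm = reflect101(x - 1, w), xp = reflect101(x + 1, w);
    for (int y = 0; y < h; ++y) {
      const int ym = reflect101(y - 1, h), yp = reflect101(y + 1, h);
      const double a = img(ym, xm), b = img(ym, x), c = img(ym, xp);
      const double d = img(y, xm), f = img(y, xp);
      const double g = img(yp, xm), i = img(yp, x), j = img(yp, xp);
      const double sx = (c + 2.0 * f + j) - (a + 2.0 * d + g);  // d/dcol
      const double sy = (g + 2.0 * i + j) - (a + 2.0 * b + c);  // d/drow
      gx(y, x) = sx;
      gy(y, x) = sy;
      mag(y, x) = std::sqrt(sx * sx + sy * sy);
    }
  }
  // non-maximum suppression along the quantized gradient direction
  const double tan225 = 0.41421356237309503, tan675 = 2.414213562373095;
  LogicalMatrix keep(h, w);
  for (int x = 0; x < w; ++x) {
    for (int y = 0; y < h; ++y) {
      const double m = mag(y, x);
      if (m <= 0) continue;
      const double ax = std::fabs(gx(y, x)), ay = std::fabs(gy(y, x));
      int dy1, dx1;
      if (ay <= tan225 * ax) { dy1 = 0; dx1 = 1; }                 // horizontal gradient
      else if (ay >= tan675 * ax) { dy1 = 1; dx1 = 0; }            // vertical
      else if (gx(y, x) * gy(y, x) > 0) { dy1 = 1; dx1 = 1; }      // main diagonal
      else { dy1 = 1; dx1 = -1; }                                  // anti-diagonal
      const int y1 = reflect101(y + dy1, h), x1 = reflect101(x + dx1, w);
      const int y2 = reflect101(y - dy1, h), x2 = reflect101(x - dx1, w);
      if (m >= mag(y1, x1) && m >= mag(y2, x2)) keep(y, x) = true;
    }
  }
  // hysteresis
  LogicalMatrix edges(h, w);
  std::vector<int> stack;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (keep(y, x) && mag(y, x) >= high && !edges(y, x)) {
        edges(y, x) = true;
        stack.push_back(x * h + y);
        while (!stack.empty()) {
          const int p = stack.back();
          stack.pop_back();
          const int py = p % h, px = p / h;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy) {
              const int qy = py + dy, qx = px + dx;
              if (qy < 0 || qy >= h || qx < 0 || qx >= w) continue;
              if (keep(qy, qx) && mag(qy, qx) >= low && !edges(qy, qx)) {
                edges(qy, qx) = true;
                stack.push_back(qx * h + qy);
              }
            }
        }
      }
  return List::create(_["edges"] = edges, _["gx"] = gx, _["gy"] = gy,
                      _["mag"] = mag);
}

struct Cand {
  int votes, row, col, radius;
};

static bool cand_less(const Cand &a, const Cand &b) {
  if (a.votes != b.votes) return a.votes > b.votes;
  if (a.row != b.row) return a.row < b.row;
  return a.col < b.col;
}

static DataFrame cand_frame(std::vector<Cand> &cands) {
  std::sort(cands.begin(), cands.end(), cand_less);
  const int n = (int)cands.size();
  IntegerVector row(n), col(n), rad(n), votes(n);
  for (int i = 0; i < n; ++i) {
    row[i] = cands[i].row + 1;  // 1-based for R
    col[i] = cands[i].col + 1;
    rad[i] = cands[i].radius;
    votes[i] = cands[i].votes;
  }
  return DataFrame::create(_["center_row"] = row, _["center_col"] = col,
                           _["radius_px"] = rad, _["votes"] = votes);
}

// Gradient-voting Hough circle stage.  Each edge pixel votes along its
// gradient direction (both senses) for centers at distances rmin..rmax;
// candidate centers are 3x3 local accumulator maxima with votes >=
// vote_threshold; the radius per center is the mode of in-range
// edge-pixel distances (ties -> smaller radius).
// [[Rcpp::export]]
List cpp_hough_gradient(LogicalMatrix edges, NumericMatrix gx,
                        NumericMatrix gy, int rmin, int rmax,
                        double vote_threshold) {
  const int h = edges.nrow(), w = edges.ncol();
  IntegerMatrix acc(h, w);
  std::vector<int> ey, ex;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y)
      if (edges(y, x)) { ey.push_back(y); ex.push_back(x); }
  const size_t ne = ey.size();
  for (size_t e = 0; e < ne; ++e) {
    const int y = ey[e], x = ex[e];
    const double sx = gx(y, x), sy = gy(y, x);
    const double m = std::sqrt(sx * sx + sy * sy);
    if (m <= 0) continue;
    const double uy = sy / m, ux = sx / m;
    for (int s = -1; s <= 1; s += 2) {
      int py = INT_MIN, px = INT_MIN;
      for (int d = rmin; d <= rmax; ++d) {
        const int cy = (int)std::lround(y + s * d * uy);
        const int cx = (int)std::lround(x + s * d * ux);
        if (cy == py && cx == px) continue;
        py = cy; px = cx;
        if (cy >= 0 && cy < h && cx >= 0 && cx < w) acc(cy, cx)++;
      }
    }
  }
  // local maxima (plateaus resolved to the first cell in column-major order)
  std::vector<Cand> cands;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      const int v = acc(y, x);
      if (v < vote_threshold) continue;
      bool is_max = true;
      for (int dx = -1; dx <= 1 && is_max; ++dx)
        for (int dy = -1; dy <= 1 && is_max; ++dy) {
          if (dx == 0 && dy == 0) continue;
          const int qy = y + dy, qx = x + dx;
          if (qy < 0 || qy >= h || qx < 0 || qx >= w) continue;
          const int u = acc(qy, qx);
          if (u > v) is_max = false;
          else if (u == v && (qx * h + qy) < (x * h + y)) is_max = false;
        }
      if (is_max) cands.push_back(Cand{v, y, x, 0});
    }
  // radius estimation: mode of edge distances in [rmin, rmax]
  const int nr = rmax - rmin + 1;
  std::vector<int> bins(nr);
  const double dmax2 = (double)(rmax + 1) * (rmax + 1);
  for (size_t c = 0; c < cands.size(); ++c) {
    std::fill(bins.begin(), bins.end(), 0);
    for (size_t e = 0; e < ne; ++e) {
      const double dy = ey[e] - cands[c].row, dx = ex[e] - cands[c].col;
      const double d2 = dy * dy + dx * dx;
      if (d2 > dmax2) continue;
      const int d = (int)std::lround(std::sqrt(d2));
      if (d >= rmin && d <= rmax) bins[d - rmin]++;
    }
    int best = 0;
    for (int k = 1; k < nr; ++k)
      if (bins[k] > bins[best]) best = k;
    cands[c].radius = rmin + best;
  }
  return List::create(_["candidates"] = cand_frame(cands),
                      _["accumulator"] = acc);
}

// Exhaustive 3-D Hough accumulator (reference implementation).  Every edge
// pixel votes for the full rasterized perimeter (1 degree steps, duplicate
// accumulator cells deduplicated per edge pixel and radius).  Candidates
// are 3x3x3 local maxima with votes >= vote_threshold.
// [[Rcpp::export]]
List cpp_hough_bruteforce(LogicalMatrix edges, int rmin, int rmax,
                          double vote_threshold) {
  const int h = edges.nrow(), w = edges.ncol(), nr = rmax - rmin + 1;
  const size_t plane = (size_t)h * w;
  std::vector<int> acc(plane * nr, 0);
  std::vector<int> stamp(plane, -1);
  double ca[360], sa[360];
  for (int a = 0; a < 360; ++a) {
    const double th = a * M_PI / 180.0;
    ca[a] = std::cos(th);
    sa[a] = std::sin(th);
  }
  int token = -1;
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      if (!edges(y, x)) continue;
      for (int ri = 0; ri < nr; ++ri) {
        const int r = rmin + ri;
        ++token;
        for (int a = 0; a < 360; ++a) {
          const int cy = (int)std::lround(y - r * sa[a]);
          const int cx = (int)std::lround(x - r * ca[a]);
          if (cy < 0 || cy >= h || cx < 0 || cx >= w) continue;
          const size_t q = (size_t)cx * h + cy;
          if (stamp[q] != token) {
            stamp[q] = token;
            acc[(size_t)ri * plane + q]++;
          }
        }
      }
    }
  std::vector<Cand> cands;
  for (int ri = 0; ri < nr; ++ri)
    for (int x = 0; x < w; ++x)
      for (int y = 0; y < h; ++y) {
        const size_t self = (size_t)ri * plane + (size_t)x * h + y;
        const int v = acc[self];
        if (v < vote_threshold) continue;
        bool is_max = true;
        for (int dr = -1; dr <= 1 && is_max; ++dr) {
          if (ri + dr < 0 || ri + dr >= nr) continue;
          for (int dx = -1; dx <= 1 && is_max; ++dx)
            for (int dy = -1; dy <= 1 && is_max; ++dy) {
              if (dr == 0 && dx == 0 && dy == 0) continue;
              const int qy = y + dy, qx = x + dx;
              if (qy < 0 || qy >= h || qx < 0 || qx >= w) continue;
              const size_t q = (size_t)(ri + dr) * plane + (size_t)qx * h + qy;
              if (acc[q] > v) is_max = false;
              else if (acc[q] == v && q < self) is_max = false;
            }
        }
        if (is_max) cands.push_back(Cand{v, y, x, rmin + ri});
      }
  IntegerVector accv(acc.begin(), acc.end());
  accv.attr("dim") = IntegerVector::create(h, w, nr);
  return List::create(_["candidates"] = cand_frame(cands),
                      _["accumulator"] = accv);
}
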
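#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Label 4- or 8-connected foreground components. Returns an integer matrix of
// labels (0 = background), labels are 1..n in scan order of first pixel.
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int nn = (connectivity == 4) ? 4 : 8;
  const int *dr = (connectivity == 4) ? dr4 : dr8;
  const int *dc = (connectivity == 4) ? dc4 : dc8;
  int next = 0;
  std::vector<int> stack;
  for (int c0 = 0; c0 < W; ++c0) {
    for (int r0 = 0; r0 < H; ++r0) {
      if (!mask(r0, c0) || lab(r0, c0)) continue;
      ++next;
      stack.clear();
      stack.push_back(r0 + c0 * H);
      lab(r0, c0) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int r = p % H, c = p / H;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) && !lab(rr, cc)) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Zhang-Suen thinning to a 1-pixel-wide 8-connected skeleton.
// [[Rcpp::export(name = ".cpp_thin")]]
LogicalMatrix cpp_thin(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  LogicalMatrix img(clone(mask));
  std::vector<int> kill;
  bool changed = true;
  // neighbours P2..P9 clockwise from north
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 1; c < W - 1; ++c) {
        for (int r = 1; r < H - 1; ++r) {
          if (!img(r, c)) continue;
          int p[8], B = 0, A = 0;
          for (int k = 0; k < 8; ++k) {
            p[k] = img(r + dr[k], c + dc[k]) ? 1 : 0;
            B += p[k];
          }
          for (int k = 0; k < 8; ++k)
            if (p[k] == 0 && p[(k + 1) % 8] == 1) ++A;
          if (B < 2 || B > 6 || A != 1) continue;
          if (pass == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;  // P2*P4*P6
            if (p[2] * p[4] * p[6] != 0) continue;  // P4*P6*P8
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;  // P2*P4*P8
            if (p[0] * p[4] * p[6] != 0) continue;  // P2*P6*P8
          }
          kill.push_back(r + c * H);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i] % H, kill[i] / H) = false;
    }
  }
  return img;
}

static void edt_1d(const std::vector<double> &f, std::vector<double> &d,
                   std::vector<int> &v, std::vector<double> &z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Squared Euclidean distance (in pixels) from each pixel to the nearest
// background (false) pixel. Felzenszwalb & Huttenlocher two-pass transform.
// [[Rcpp::export(name = ".cpp_edt_sq")]]
NumericMatrix cpp_edt_sq(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  const double INF = 1e18;
  NumericMatrix out(H, W);
  int n = std::max(H, W);
  std::vector<double> f(n), d(n), z(n + 1);
  std::vector<int> v(n);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) f[r] = mask(r, c) ? INF : 0.0;
    edt_1d(f, d, v, z, H);
    for (int r = 0; r < H; ++r) out(r, c) = d[r];
  }
  for (int r = 0; r < H; ++r) {
    for (int c = 0; c < W; ++c) f[c] = out(r, c);
    edt_1d(f, d, v, z, W);
    for (int c = 0; c < W; ++c) out(r, c) = d[c];
  }
  return out;
}

// Rasterize graph edges as capsules (stadium shapes). Each pixel inside some
// capsule is labelled with the 1-based index of the edge whose centerline is
// nearest. Pixel (r, c), 1-based from R, has centre x = (c-0.5)*psx,
// y = (H-r+0.5)*psy (image row 1 = top, physical y up). Edge centrelines are
// additionally traced so every edge is at least one pixel wide.
// [[Rcpp::export(name = ".cpp_rasterize_capsules")]]
List cpp_rasterize_capsules(NumericMatrix seg, double psx, double psy, int H,
                            int W) {
  // seg columns: x1 y1 x2 y2 radius
  IntegerMatrix lab(H, W);
  NumericMatrix best(H, W);
  std::fill(best.begin(), best.end(), std::numeric_limits<double>::infinity());
  const int nE = seg.nrow();
  for (int e = 0; e < nE; ++e) {
    double x1 = seg(e, 0), y1 = seg(e, 1), x2 = seg(e, 2), y2 = seg(e, 3),
           rad = seg(e, 4);
    double xmin = std::min(x1, x2) - rad, xmax = std::max(x1, x2) + rad;
    double ymin = std::min(y1, y2) - rad, ymax = std::max(y1, y2) + rad;
    int cmin = std::max(0, (int)std::floor(xmin / psx - 0.5) - 1);
    int cmax = std::min(W - 1, (int)std::ceil(xmax / psx - 0.5) + 1);
    int rmin = std::max(0, (int)std::floor((H - ymax / psy) - 1.0) - 1);
    int rmax = std::min(H - 1, (int)std::ceil(H - ymin / psy) + 1);
    double dx = x2 - x1, dy = y2 - y1;
    double L2 = dx * dx + dy * dy;
    for (int c = cmin; c <= cmax; ++c) {
      double px = (c + 0.5) * psx;
      for (int r = rmin; r <= rmax; ++r) {
        double py = (H - r - 0.5) * psy;
        double t = L2 > 0 ? ((px - x1) * dx + (py - y1) * dy) / L2 : 0.0;
        t = std::max(0.0, std::min(1.0, t));
        double qx = x1 + t * dx - px, qy = y1 + t * dy - py;
        double d = std::sqrt(qx * qx + qy * qy);
        if (d <= rad && d < best(r, c)) {
          best(r, c) = d;
          lab(r, c) = e + 1;
        }
      }
    }
    // centreline trace (guarantees >= 1 px width)
    double Llen = std::sqrt(L2);
    int nstep = std::max(1, (int)std::ceil(Llen / (0.5 * std::min(psx, psy))));
    for (int k = 0; k <= nstep; ++k) {
      double t = (double)k / nstep;
      double px = x1 + t * dx, py = y1 + t * dy;
      int c = (int)std::floor(px / psx);
      int r = H - 1 - (int)std::floor(py / psy);
      if (r < 0 || r >= H || c < 0 || c >= W) continue;
      if (lab(r, c) == 0) {
        lab(r, c) = e + 1;
        best(r, c) = 0.0;
      }
    }
  }
  return List::create(_["edge_id"] = lab, _["dist"] = best);
}
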
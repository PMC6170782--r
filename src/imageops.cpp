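// Raster kernels shared by the rendering, boundary and flow pipelines.
// Matrices follow the R convention m[row, col] = m[y, x]; pixel (i, j) is
// centred at world (origin_x + (j - 0.5) * px, origin_y + (i - 0.5) * px).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Separable correlation (no kernel flip), replicate padding.
// ky runs along rows (y), kx along columns (x); both have odd length.
// [[Rcpp::export]]
NumericMatrix sep_filter2_cpp(NumericMatrix m, NumericVector ky, NumericVector kx) {
  const int nr = m.nrow(), nc = m.ncol();
  const int hy = (ky.size() - 1) / 2, hx = (kx.size() - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double s = 0.0;
      for (int u = -hy; u <= hy; ++u)
        s += ky[u + hy] * m(clampi(i + u, 0, nr - 1), j);
      tmp(i, j) = s;
    }
  }
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double s = 0.0;
      for (int u = -hx; u <= hx; ++u)
        s += kx[u + hx] * tmp(i, clampi(j + u, 0, nc - 1));
      out(i, j) = s;
    }
  }
  return out;
}

// Separable box mean of odd width w, replicate padding, via running sums.
// [[Rcpp::export]]
NumericMatrix box_filter_cpp(NumericMatrix m, int w) {
  const int nr = m.nrow(), nc = m.ncol();
  const int h = (w - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    double s = 0.0;
    for (int u = -h; u <= h; ++u) s += m(clampi(u, 0, nr - 1), j);
    tmp(0, j) = s / w;
    for (int i = 1; i < nr; ++i) {
      s += m(clampi(i + h, 0, nr - 1), j) - m(clampi(i - 1 - h, 0, nr - 1), j);
      tmp(i, j) = s / w;
    }
  }
  for (int i = 0; i < nr; ++i) {
    double s = 0.0;
    for (int u = -h; u <= h; ++u) s += tmp(i, clampi(u, 0, nc - 1));
    out(i, 0) = s / w;
    for (int j = 1; j < nc; ++j) {
      s += tmp(i, clampi(j + h, 0, nc - 1)) - tmp(i, clampi(j - 1 - h, 0, nc - 1));
      out(i, j) = s / w;
    }
  }
  return out;
}

// Bilinear sampling of m at (mapy, mapx) in 1-based matrix coordinates,
// clamped at the borders.
// [[Rcpp::export]]
NumericMatrix warp_bilinear_cpp(NumericMatrix m, NumericMatrix mapy, NumericMatrix mapx) {
  const int nr = m.nrow(), nc = m.ncol();
  const int onr = mapy.nrow(), onc = mapy.ncol();
  NumericMatrix out(onr, onc);
  for (int j = 0; j < onc; ++j) {
    for (int i = 0; i < onr; ++i) {
      double yy = mapy(i, j) - 1.0, xx = mapx(i, j) - 1.0;
      if (yy < 0) yy = 0; if (yy > nr - 1) yy = nr - 1;
      if (xx < 0) xx = 0; if (xx > nc - 1) xx = nc - 1;
      int y0 = (int)std::floor(yy), x0 = (int)std::floor(xx);
      int y1 = y0 + 1 < nr ? y0 + 1 : y0;
      int x1 = x0 + 1 < nc ? x0 + 1 : x0;
      double fy = yy - y0, fx = xx - x0;
      out(i, j) = (1 - fy) * ((1 - fx) * m(y0, x0) + fx * m(y0, x1)) +
                  fy * ((1 - fx) * m(y1, x0) + fx * m(y1, x1));
    }
  }
  return out;
}

// Nearest-neighbour sampling for discrete label rasters.
// [[Rcpp::export]]
IntegerMatrix warp_nearest_int_cpp(IntegerMatrix m, NumericMatrix mapy, NumericMatrix mapx) {
  const int nr = m.nrow(), nc = m.ncol();
  const int onr = mapy.nrow(), onc = mapy.ncol();
  IntegerMatrix out(onr, onc);
  for (int j = 0; j < onc; ++j) {
    for (int i = 0; i < onr; ++i) {
      int yy = clampi((int)std::lround(mapy(i, j) - 1.0), 0, nr - 1);
      int xx = clampi((int)std::lround(mapx(i, j) - 1.0), 0, nc - 1);
      out(i, j) = m(yy, xx);
    }
  }
  return out;
}

static inline double point_seg_dist(double px, double py,
                                    double cx, double cy, double dx, double dy, double h) {
  double s = (px - cx) * dx + (py - cy) * dy;
  if (s < -h) s = -h; else if (s > h) s = h;
  double qx = cx + s * dx - px, qy = cy + s * dy - py;
  return std::sqrt(qx * qx + qy * qy);
}

// Rasterize capsules: intensity is the per-cell value scaled by the
// edge-antialiased coverage clamp(0.5 + (r - d)/px); index is the owning
// (closest-axis) cell, 0 outside any capsule.
// [[Rcpp::export]]
List rasterize_cells_cpp(NumericVector x, NumericVector y,
                         NumericVector dx, NumericVector dy,
                         NumericVector len, NumericVector radius,
                         NumericVector value,
                         double origin_x, double origin_y, double pixel_size,
                         int nrow_img, int ncol_img) {
  NumericMatrix img(nrow_img, ncol_img);
  IntegerMatrix idx(nrow_img, ncol_img);
  NumericMatrix best(nrow_img, ncol_img);
  std::fill(best.begin(), best.end(), 1e300);
  const int n = x.size();
  for (int c = 0; c < n; ++c) {
    double h = len[c] / 2.0, r = radius[c];
    double ext = h + r + pixel_size;
    int j0 = clampi((int)std::floor((x[c] - ext - origin_x) / pixel_size), 0, ncol_img - 1);
    int j1 = clampi((int)std::ceil((x[c] + ext - origin_x) / pixel_size), 0, ncol_img - 1);
    int i0 = clampi((int)std::floor((y[c] - ext - origin_y) / pixel_size), 0, nrow_img - 1);
    int i1 = clampi((int)std::ceil((y[c] + ext - origin_y) / pixel_size), 0, nrow_img - 1);
    for (int i = i0; i <= i1; ++i) {
      double py = origin_y + (i + 0.5) * pixel_size;
      for (int j = j0; j <= j1; ++j) {
        double px = origin_x + (j + 0.5) * pixel_size;
        double d = point_seg_dist(px, py, x[c], y[c], dx[c], dy[c], h);
        double cov = 0.5 + (r - d) / pixel_size;
        if (cov <= 0.0) continue;
        if (cov > 1.0) cov = 1.0;
        if (d < best(i, j)) {
          best(i, j) = d;
          idx(i, j) = c + 1;
          img(i, j) = cov * value[c];
        }
      }
    }
  }
  return List::create(_["intensity"] = img, _["index"] = idx);
}

// Displacement of arbitrary world points under the nearest-cell
// rigid+stretch motion model (see truth_field_cpp).  Points outside every
// cell are carried by their nearest cell.
// [[Rcpp::export]]
List truth_points_cpp(NumericVector prex, NumericVector prey,
                      NumericVector dx, NumericVector dy,
                      NumericVector len, NumericVector radius,
                      NumericVector dispx, NumericVector dispy, NumericVector rot,
                      NumericVector stretch,
                      NumericVector px_, NumericVector py_) {
  const int n = prex.size(), np = px_.size();
  NumericVector ou(np), ov(np);
  if (n == 0) return List::create(_["dx"] = ou, _["dy"] = ov);
  double maxext = 0.0, xmin = prex[0], ymin = prey[0];
  for (int i = 0; i < n; ++i) {
    double e = len[i] / 2.0 + radius[i];
    if (e > maxext) maxext = e;
    if (prex[i] < xmin) xmin = prex[i];
    if (prey[i] < ymin) ymin = prey[i];
  }
  const double g = 2.0 * maxext + 1e-9;
  int ngx = 1, ngy = 1;
  std::vector<int> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (int)std::floor((prex[i] - xmin) / g);
    gy[i] = (int)std::floor((prey[i] - ymin) / g);
    if (gx[i] + 1 > ngx) ngx = gx[i] + 1;
    if (gy[i] + 1 > ngy) ngy = gy[i] + 1;
  }
  std::vector<int> head((size_t)ngx * ngy, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int b = gy[i] * ngx + gx[i];
    nxt[i] = head[b];
    head[b] = i;
  }
  for (int k = 0; k < np; ++k) {
    double px = px_[k], py = py_[k];
    int cgx = (int)std::floor((px - xmin) / g);
    int cgy = (int)std::floor((py - ymin) / g);
    int bestc = -1;
    double bestd = 1e300;
    for (int ring = 1; ring <= 6 && bestc < 0; ++ring) {
      for (int oy = -ring; oy <= ring; ++oy) {
        int cy = cgy + oy;
        if (cy < 0 || cy >= ngy) continue;
        for (int ox = -ring; ox <= ring; ++ox) {
          int cx = cgx + ox;
          if (cx < 0 || cx >= ngx) continue;
          for (int c = head[cy * ngx + cx]; c != -1; c = nxt[c]) {
            double d = point_seg_dist(px, py, prex[c], prey[c], dx[c], dy[c], len[c] / 2.0);
            if (d < bestd) { bestd = d; bestc = c; }
          }
        }
      }
    }
    if (bestc < 0) {
      for (int c = 0; c < n; ++c) {
        double d = point_seg_dist(px, py, prex[c], prey[c], dx[c], dy[c], len[c] / 2.0);
        if (d < bestd) { bestd = d; bestc = c; }
      }
    }
    double qx = px - prex[bestc], qy = py - prey[bestc];
    double ax = dx[bestc], ay = dy[bestc];
    double s = qx * ax + qy * ay;
    double nrm = -qx * ay + qy * ax;
    double h = len[bestc] / 2.0;
    double sseg = s < -h ? -h : (s > h ? h : s);
    double spost = sseg * stretch[bestc] + (s - sseg);
    double lx = spost * ax - nrm * ay;
    double ly = spost * ay + nrm * ax;
    double ct = std::cos(rot[bestc]), st = std::sin(rot[bestc]);
    ou[k] = prex[bestc] + dispx[bestc] + ct * lx - st * ly - px;
    ov[k] = prey[bestc] + dispy[bestc] + st * lx + ct * ly - py;
  }
  return List::create(_["dx"] = ou, _["dy"] = ov);
}

// Ground-truth pixel velocities by nearest-cell assignment.  Cells are
// given at their pre-frame poses (prex, prey, dx, dy of the pre-frame
// orientation, len the PRE-frame axis length); each carries a net centre
// displacement (dispx, dispy), rotation rot and axial stretch factor over
// the frame.  For every mask pixel the nearest pre-frame axis segment is
// found (grid-accelerated); the pixel's axial coordinate along the segment
// is stretched (cap overhang rides along with the pole), the offset is
// rotated by rot, and the centre displacement added; the material-point
// displacement is reported in pixels.
// [[Rcpp::export]]
List truth_field_cpp(NumericVector prex, NumericVector prey,
                     NumericVector dx, NumericVector dy,
                     NumericVector len, NumericVector radius,
                     NumericVector dispx, NumericVector dispy, NumericVector rot,
                     NumericVector stretch,
                     LogicalMatrix mask,
                     double origin_x, double origin_y, double pixel_size) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int n = prex.size();
  NumericMatrix u(nr, nc), v(nr, nc);
  if (n == 0) return List::create(_["u"] = u, _["v"] = v);
  double maxext = 0.0, xmin = prex[0], ymin = prey[0];
  for (int i = 0; i < n; ++i) {
    double e = len[i] / 2.0 + radius[i];
    if (e > maxext) maxext = e;
    if (prex[i] < xmin) xmin = prex[i];
    if (prey[i] < ymin) ymin = prey[i];
  }
  const double g = 2.0 * maxext + 1e-9;
  int ngx = 1, ngy = 1;
  std::vector<int> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (int)std::floor((prex[i] - xmin) / g);
    gy[i] = (int)std::floor((prey[i] - ymin) / g);
    if (gx[i] + 1 > ngx) ngx = gx[i] + 1;
    if (gy[i] + 1 > ngy) ngy = gy[i] + 1;
  }
  std::vector<int> head((size_t)ngx * ngy, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int b = gy[i] * ngx + gx[i];
    nxt[i] = head[b];
    head[b] = i;
  }
  for (int i = 0; i < nr; ++i) {
    double py = origin_y + (i + 0.5) * pixel_size;
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) { u(i, j) = NA_REAL; v(i, j) = NA_REAL; continue; }
      double px = origin_x + (j + 0.5) * pixel_size;
      int cgx = (int)std::floor((px - xmin) / g);
      int cgy = (int)std::floor((py - ymin) / g);
      int bestc = -1;
      double bestd = 1e300;
      for (int ring = 1; ring <= 6 && bestc < 0; ++ring) {
        for (int oy = -ring; oy <= ring; ++oy) {
          int cy = cgy + oy;
          if (cy < 0 || cy >= ngy) continue;
          for (int ox = -ring; ox <= ring; ++ox) {
            int cx = cgx + ox;
            if (cx < 0 || cx >= ngx) continue;
            for (int c = head[cy * ngx + cx]; c != -1; c = nxt[c]) {
              double d = point_seg_dist(px, py, prex[c], prey[c], dx[c], dy[c], len[c] / 2.0);
              if (d < bestd) { bestd = d; bestc = c; }
            }
          }
        }
      }
      if (bestc < 0) {   // fall back to linear scan (isolated far pixel)
        for (int c = 0; c < n; ++c) {
          double d = point_seg_dist(px, py, prex[c], prey[c], dx[c], dy[c], len[c] / 2.0);
          if (d < bestd) { bestd = d; bestc = c; }
        }
      }
      double qx = px - prex[bestc], qy = py - prey[bestc];
      // decompose into axial / transverse components of the pre-frame axis
      double ax = dx[bestc], ay = dy[bestc];
      double s = qx * ax + qy * ay;
      double nrm = -qx * ay + qy * ax;
      double h = len[bestc] / 2.0;
      double sseg = s < -h ? -h : (s > h ? h : s);
      double spost = sseg * stretch[bestc] + (s - sseg);
      double lx = spost * ax - nrm * ay;
      double ly = spost * ay + nrm * ax;
      double ct = std::cos(rot[bestc]), st = std::sin(rot[bestc]);
      double mx = prex[bestc] + dispx[bestc] + ct * lx - st * ly;
      double my = prey[bestc] + dispy[bestc] + st * lx + ct * ly;
      u(i, j) = (mx - px) / pixel_size;
      v(i, j) = (my - py) / pixel_size;
    }
  }
  return List::create(_["u"] = u, _["v"] = v);
}

// Zhang-Suen morphological thinning to a 1-pixel-wide 8-connected skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  std::vector<unsigned char> img((size_t)nr * nc, 0);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      img[(size_t)j * nr + i] = m(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> unsigned char {
    if (i < 0 || i >= nr || j < 0 || j >= nc) return 0;
    return img[(size_t)j * nr + i];
  };
  // Guo-Hall two-subiteration thinning (preserves diagonal lines that the
  // simpler schemes erode away entirely)
  bool changed = true;
  std::vector<std::pair<int, int>> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!at(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          unsigned char p2 = at(i - 1, j), p3 = at(i - 1, j + 1), p4 = at(i, j + 1),
                        p5 = at(i + 1, j + 1), p6 = at(i + 1, j), p7 = at(i + 1, j - 1),
                        p8 = at(i, j - 1), p9 = at(i - 1, j - 1);
          int C = ((!p2) & (p3 | p4)) + ((!p4) & (p5 | p6)) +
                  ((!p6) & (p7 | p8)) + ((!p8) & (p9 | p2));
          int N1 = (p9 | p2) + (p3 | p4) + (p5 | p6) + (p7 | p8);
          int N2 = (p2 | p3) + (p4 | p5) + (p6 | p7) + (p8 | p9);
          int N = N1 < N2 ? N1 : N2;
          int m = pass == 0 ? ((p6 | p7 | (!p9)) & p8) : ((p2 | p3 | (!p5)) & p4);
          if (C == 1 && N >= 2 && N <= 3 && m == 0)
            kill.push_back({i, j});
        }
      }
      for (auto &pr : kill) img[(size_t)pr.second * nr + pr.first] = 0;
      if (!kill.empty()) changed = true;
    }
  }
  // staircase pruning: a corner pixel whose only two neighbours are one
  // axial N/S and one axial E/W (themselves 8-adjacent through the
  // diagonal) is redundant for 8-connectivity; removing it turns
  // 4-connected zigzags into clean diagonals so pixel counts do not
  // inflate on rotated lines.
  bool pruned = true;
  while (pruned) {
    pruned = false;
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!at(i, j)) continue;
        unsigned char p2 = at(i - 1, j), p4 = at(i, j + 1),
                      p6 = at(i + 1, j), p8 = at(i, j - 1);
        unsigned char p3 = at(i - 1, j + 1), p5 = at(i + 1, j + 1),
                      p7 = at(i + 1, j - 1), p9 = at(i - 1, j - 1);
        int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
        if (B != 2) continue;
        if ((p2 && p4) || (p4 && p6) || (p6 && p8) || (p8 && p2)) {
          img[(size_t)j * nr + i] = 0;
          pruned = true;
        }
      }
    }
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      out(i, j) = img[(size_t)j * nr + i] != 0;
  return out;
}

// Line integral convolution: smear a noise texture along streamlines of
// (u, v) (pixels/frame), bidirectional Euler integration with unit-speed
// normalization, klen steps of 1 px each way.
// [[Rcpp::export]]
NumericMatrix lic_cpp(NumericMatrix u, NumericMatrix v, NumericMatrix noise, int klen) {
  const int nr = u.nrow(), nc = u.ncol();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = noise(i, j);
      double wsum = 1.0;
      for (int dir = -1; dir <= 1; dir += 2) {
        double x = j, y = i;
        for (int s = 0; s < klen; ++s) {
          int yi = clampi((int)std::lround(y), 0, nr - 1);
          int xi = clampi((int)std::lround(x), 0, nc - 1);
          double uu = u(yi, xi), vv = v(yi, xi);
          double sp = std::sqrt(uu * uu + vv * vv);
          if (sp < 1e-9) break;
          x += dir * uu / sp;
          y += dir * vv / sp;
          if (x < 0 || x > nc - 1 || y < 0 || y > nr - 1) break;
          yi = clampi((int)std::lround(y), 0, nr - 1);
          xi = clampi((int)std::lround(x), 0, nc - 1);
          acc += noise(yi, xi);
          wsum += 1.0;
        }
      }
      out(i, j) = acc / wsum;
    }
  }
  return out;
}
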
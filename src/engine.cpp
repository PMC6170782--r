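// Capsule-cell geometry and overdamped colony mechanics.
//
// Cells are 2-D spherocylinders: an axis segment of length L centred at
// (x, y) with unit direction (dx, dy) and cap radius r.  Contacts are
// resolved between axis segments; repulsion is a linear penalty on overlap,
// adhesion is a viscous drag on the transverse component of the relative
// contact-point velocity.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Closest points between two segments given centre/direction/length.
// Segment i is p_i + s * d_i, s in [-L_i/2, L_i/2].  Returns parameters
// (s, t); caller reconstructs the points.
static void seg_closest_params(double p1x, double p1y, double d1x, double d1y, double h1,
                               double p2x, double p2y, double d2x, double d2y, double h2,
                               double &s, double &t) {
  const double wx = p1x - p2x, wy = p1y - p2y;
  const double b = d1x * d2x + d1y * d2y;       // d1 . d2
  const double e = wx * d1x + wy * d1y;         // w . d1
  const double f = wx * d2x + wy * d2y;         // w . d2
  const double den = 1.0 - b * b;
  if (den > 1e-12) {
    s = clampd((b * f - e) / den, -h1, h1);
  } else {
    // parallel: project the other centre
    s = clampd(-e, -h1, h1);
  }
  t = clampd(s * b + f, -h2, h2);
  s = clampd(t * b - e, -h1, h1);
}

// [[Rcpp::export]]
List closest_points_cpp(NumericVector p1, NumericVector d1, double L1,
                        NumericVector p2, NumericVector d2, double L2) {
  double s, t;
  seg_closest_params(p1[0], p1[1], d1[0], d1[1], L1 / 2.0,
                     p2[0], p2[1], d2[0], d2[1], L2 / 2.0, s, t);
  double ax = p1[0] + s * d1[0], ay = p1[1] + s * d1[1];
  double bx = p2[0] + t * d2[0], by = p2[1] + t * d2[1];
  double dist = std::sqrt((ax - bx) * (ax - bx) + (ay - by) * (ay - by));
  return List::create(_["point_a"] = NumericVector::create(ax, ay),
                      _["point_b"] = NumericVector::create(bx, by),
                      _["distance"] = dist,
                      _["s"] = s, _["t"] = t);
}

// Internal contact record.
struct Contact {
  int i, j;                 // 0-based cell indices, i < j
  double ax, ay, bx, by;    // closest points on i and j
  double nx, ny;            // unit normal from i to j
  double dist, overlap;     // axis distance; 2r - dist (+margin handled by caller)
  double k;                 // pairwise adhesion, min(adhesin_i, adhesin_j)
};

// Uniform-grid broad phase + narrow phase.  Interaction radius per pair is
// len_i/2 + r_i + len_j/2 + r_j + margin, bounded by 2*maxext + margin with
// maxext = max(len/2 + r); a grid of that bin size makes the 3x3 block
// neighbourhood sufficient.
static void find_contacts(const std::vector<double> &x, const std::vector<double> &y,
                          const std::vector<double> &dx, const std::vector<double> &dy,
                          const std::vector<double> &len, const std::vector<double> &rad,
                          const std::vector<double> &adh, double margin,
                          std::vector<Contact> &out) {
  const int n = (int)x.size();
  out.clear();
  if (n < 2) return;
  double maxext = 0.0, xmin = x[0], ymin = y[0];
  for (int i = 0; i < n; ++i) {
    double e = len[i] / 2.0 + rad[i];
    if (e > maxext) maxext = e;
    if (x[i] < xmin) xmin = x[i];
    if (y[i] < ymin) ymin = y[i];
  }
  const double g = 2.0 * maxext + margin + 1e-9;
  std::vector<int> gx(n), gy(n);
  int nx = 1, ny = 1;
  for (int i = 0; i < n; ++i) {
    gx[i] = (int)std::floor((x[i] - xmin) / g);
    gy[i] = (int)std::floor((y[i] - ymin) / g);
    if (gx[i] + 1 > nx) nx = gx[i] + 1;
    if (gy[i] + 1 > ny) ny = gy[i] + 1;
  }
  // bucket fill (counting sort into flat grid)
  std::vector<int> head((size_t)nx * ny, -1), nxt(n, -1);
  for (int i = 0; i < n; ++i) {
    int b = gy[i] * nx + gx[i];
    nxt[i] = head[b];
    head[b] = i;
  }
  for (int i = 0; i < n; ++i) {
    for (int oy = -1; oy <= 1; ++oy) {
      int cy = gy[i] + oy;
      if (cy < 0 || cy >= ny) continue;
      for (int ox = -1; ox <= 1; ++ox) {
        int cx = gx[i] + ox;
        if (cx < 0 || cx >= nx) continue;
        for (int j = head[cy * nx + cx]; j != -1; j = nxt[j]) {
          if (j <= i) continue;
          double rr = len[i] / 2.0 + rad[i] + len[j] / 2.0 + rad[j] + margin;
          double ddx = x[j] - x[i], ddy = y[j] - y[i];
          if (ddx * ddx + ddy * ddy > rr * rr) continue;
          double s, t;
          seg_closest_params(x[i], y[i], dx[i], dy[i], len[i] / 2.0,
                             x[j], y[j], dx[j], dy[j], len[j] / 2.0, s, t);
          double ax = x[i] + s * dx[i], ay = y[i] + s * dy[i];
          double bx = x[j] + t * dx[j], by = y[j] + t * dy[j];
          double vx = bx - ax, vy = by - ay;
          double dist = std::sqrt(vx * vx + vy * vy);
          if (dist >= rad[i] + rad[j] + margin) continue;
          Contact c;
          c.i = i; c.j = j;
          c.ax = ax; c.ay = ay; c.bx = bx; c.by = by;
          if (dist > 1e-12) {
            c.nx = vx / dist; c.ny = vy / dist;
          } else {
            c.nx = 1.0; c.ny = 0.0;   // deterministic degenerate tie-break
          }
          c.dist = dist;
          c.overlap = rad[i] + rad[j] - dist;
          c.k = adh[i] < adh[j] ? adh[i] : adh[j];
          out.push_back(c);
        }
      }
    }
  }
}

static std::vector<double> as_vec(NumericVector v) {
  return std::vector<double>(v.begin(), v.end());
}

// [[Rcpp::export]]
NumericMatrix contacts_grid_cpp(NumericVector x, NumericVector y,
                                NumericVector dx, NumericVector dy,
                                NumericVector len, NumericVector radius,
                                NumericVector adhesin, double margin) {
  std::vector<Contact> cs;
  std::vector<double> vx = as_vec(x), vy = as_vec(y), vdx = as_vec(dx), vdy = as_vec(dy),
                      vl = as_vec(len), vr = as_vec(radius), va = as_vec(adhesin);
  find_contacts(vx, vy, vdx, vdy, vl, vr, va, margin, cs);
  NumericMatrix m((int)cs.size(), 11);
  for (size_t k = 0; k < cs.size(); ++k) {
    const Contact &c = cs[k];
    m(k, 0) = c.i + 1; m(k, 1) = c.j + 1;
    m(k, 2) = c.ax; m(k, 3) = c.ay; m(k, 4) = c.bx; m(k, 5) = c.by;
    m(k, 6) = c.nx; m(k, 7) = c.ny;
    m(k, 8) = c.overlap; m(k, 9) = c.dist; m(k, 10) = c.k;
  }
  colnames(m) = CharacterVector::create("i", "j", "ax", "ay", "bx", "by",
                                        "nx", "ny", "overlap", "dist", "k_pair");
  return m;
}

// Accumulate repulsion (+ external) forces and torques for a contact set.
static void repulsion_and_external(const std::vector<Contact> &cs,
                                   const std::vector<double> &x, const std::vector<double> &y,
                                   double k_contact,
                                   const std::vector<double> &fx_ext, const std::vector<double> &fy_ext,
                                   std::vector<double> &fx, std::vector<double> &fy,
                                   std::vector<double> &tq) {
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    fx[i] = fx_ext[i]; fy[i] = fy_ext[i]; tq[i] = 0.0;
  }
  for (const Contact &c : cs) {
    if (c.overlap <= 0.0) continue;
    double f = k_contact * c.overlap;
    double fxi = -f * c.nx, fyi = -f * c.ny;   // push i away from j
    fx[c.i] += fxi; fy[c.i] += fyi;
    fx[c.j] -= fxi; fy[c.j] -= fyi;
    // torques about cell centres (z-component of r x F)
    tq[c.i] += (c.ax - x[c.i]) * fyi - (c.ay - y[c.i]) * fxi;
    tq[c.j] += (c.bx - x[c.j]) * (-fyi) - (c.by - y[c.j]) * (-fxi);
  }
}

// Adhesion drag given per-cell linear and angular velocities.  Applies
// F = k_eff * v_t to cell i at its contact point (and the opposite to j),
// where v_t is the transverse (tangential) component of the relative
// velocity of the two material points and k_eff = k / (1 + k * mu) with
// mu the summed inverse drags of the pair (a per-contact backward-Euler
// coefficient keeping the explicit iteration stable at large k; linear in
// v_t throughout).
static void adhesion_forces_cpp(const std::vector<Contact> &cs,
                                const std::vector<double> &x, const std::vector<double> &y,
                                const std::vector<double> &vx, const std::vector<double> &vy,
                                const std::vector<double> &om,
                                const std::vector<double> &drag_t,
                                std::vector<double> &fx, std::vector<double> &fy,
                                std::vector<double> &tq, bool solve_pair) {
  for (const Contact &c : cs) {
    if (c.k <= 0.0) continue;
    double rax = c.ax - x[c.i], ray = c.ay - y[c.i];
    double rbx = c.bx - x[c.j], rby = c.by - y[c.j];
    // material point velocities: v + omega x r, omega x r = (-om*ry, om*rx)
    double vax = vx[c.i] - om[c.i] * ray, vay = vy[c.i] + om[c.i] * rax;
    double vbx = vx[c.j] - om[c.j] * rby, vby = vy[c.j] + om[c.j] * rbx;
    double relx = vbx - vax, rely = vby - vay;
    // tangent: unit vector perpendicular to the contact normal
    double tx = -c.ny, ty = c.nx;
    double vt = relx * tx + rely * ty;
    // solve_pair: the supplied velocities are the pre-adhesion iterate, so
    // solve the pair's instantaneous force balance F = k v_t(F) exactly;
    // otherwise apply the literal drag law at the given velocities.
    double keff = c.k;
    if (solve_pair) {
      double mu = 1.0 / drag_t[c.i] + 1.0 / drag_t[c.j];
      keff = c.k / (1.0 + c.k * mu);
    }
    double fxa = keff * vt * tx, fya = keff * vt * ty;   // drags i along with j
    fx[c.i] += fxa; fy[c.i] += fya;
    fx[c.j] -= fxa; fy[c.j] -= fya;
    tq[c.i] += rax * fya - ray * fxa;
    tq[c.j] += rbx * (-fya) - rby * (-fxa);
  }
}

// [[Rcpp::export]]
List compute_forces_cpp(NumericVector x, NumericVector y,
                        NumericVector dx, NumericVector dy,
                        NumericVector len, NumericVector radius, NumericVector adhesin,
                        NumericVector vx, NumericVector vy, NumericVector om,
                        double k_contact, double gamma_t, double margin,
                        bool adhesion_on) {
  // Diagnostic entry point: forces and torques from repulsion plus adhesion
  // at the supplied velocities (no external forces).
  std::vector<double> X = as_vec(x), Y = as_vec(y), DX = as_vec(dx), DY = as_vec(dy),
                      L = as_vec(len), R = as_vec(radius), A = as_vec(adhesin);
  int n = (int)X.size();
  std::vector<Contact> cs;
  find_contacts(X, Y, DX, DY, L, R, A, margin, cs);
  std::vector<double> fx(n), fy(n), tq(n), zx(n, 0.0), zy(n, 0.0), drag(n);
  repulsion_and_external(cs, X, Y, k_contact, zx, zy, fx, fy, tq);
  for (int i = 0; i < n; ++i) drag[i] = gamma_t * (L[i] + 2.0 * R[i]);
  if (adhesion_on) {
    std::vector<double> VX = as_vec(vx), VY = as_vec(vy), OM = as_vec(om);
    adhesion_forces_cpp(cs, X, Y, VX, VY, OM, drag, fx, fy, tq, false);
  }
  return List::create(_["fx"] = NumericVector(fx.begin(), fx.end()),
                      _["fy"] = NumericVector(fy.begin(), fy.end()),
                      _["torque"] = NumericVector(tq.begin(), tq.end()),
                      _["n_contacts"] = (int)cs.size());
}

// Overdamped constraint relaxation.  Iterates sub-steps of size dt_sub:
//   v = F / (gamma_t * (L + 2r)),  omega = tau / (gamma_r * (L + 2r)^3)
// with F composed of contact repulsion, persistent external forces and
// (optionally) adhesion drag evaluated at the current iterate's tentative
// velocities.  Stops when the worst overlap is within overlap_tol (only if
// no external forces act) or after relax_iters sub-steps.
// [[Rcpp::export]]
List relax_cpp(NumericVector x0, NumericVector y0,
               NumericVector dx0, NumericVector dy0,
               NumericVector len, NumericVector radius, NumericVector adhesin,
               NumericVector fext_x, NumericVector fext_y,
               double k_contact, double gamma_t, double gamma_r,
               double dt_sub, int relax_iters, double overlap_tol,
               double margin, bool adhesion_on) {
  std::vector<double> x = as_vec(x0), y = as_vec(y0), dx = as_vec(dx0), dy = as_vec(dy0),
                      L = as_vec(len), R = as_vec(radius), A = as_vec(adhesin),
                      fex = as_vec(fext_x), fey = as_vec(fext_y);
  const int n = (int)x.size();
  bool has_ext = false;
  for (int i = 0; i < n; ++i)
    if (fex[i] != 0.0 || fey[i] != 0.0) { has_ext = true; break; }
  std::vector<double> fx(n), fy(n), tq(n), vx(n), vy(n), om(n), drag(n), drag_r(n), rot(n, 0.0);
  for (int i = 0; i < n; ++i) {
    double Le = L[i] + 2.0 * R[i];
    drag[i] = gamma_t * Le;
    drag_r[i] = gamma_r * Le * Le * Le;
  }
  std::vector<Contact> cs;
  double max_ov = 0.0;
  int used = 0;
  // adhesion drag is evaluated at the previous sub-step's velocities (one
  // lag iterate): drag chains then propagate one contact per sub-step and
  // settle into the quasi-static coupled profile
  std::fill(vx.begin(), vx.end(), 0.0);
  std::fill(vy.begin(), vy.end(), 0.0);
  std::fill(om.begin(), om.end(), 0.0);
  for (int it = 0; it < relax_iters; ++it) {
    find_contacts(x, y, dx, dy, L, R, A, margin, cs);
    max_ov = 0.0;
    for (const Contact &c : cs)
      if (c.overlap > max_ov) max_ov = c.overlap;
    if (!has_ext && max_ov <= overlap_tol) break;
    repulsion_and_external(cs, x, y, k_contact, fex, fey, fx, fy, tq);
    if (adhesion_on)
      adhesion_forces_cpp(cs, x, y, vx, vy, om, drag, fx, fy, tq, true);
    for (int i = 0; i < n; ++i) {
      vx[i] = fx[i] / drag[i];
      vy[i] = fy[i] / drag[i];
      om[i] = tq[i] / drag_r[i];
      x[i] += vx[i] * dt_sub;
      y[i] += vy[i] * dt_sub;
      double dth = om[i] * dt_sub;
      rot[i] += dth;
      double ct = std::cos(dth), st = std::sin(dth);
      double ndx = ct * dx[i] - st * dy[i];
      double ndy = st * dx[i] + ct * dy[i];
      double nn = std::sqrt(ndx * ndx + ndy * ndy);
      dx[i] = ndx / nn; dy[i] = ndy / nn;
    }
    ++used;
  }
  NumericVector ddx(n), ddy(n);
  for (int i = 0; i < n; ++i) {
    ddx[i] = x[i] - x0[i];
    ddy[i] = y[i] - y0[i];
  }
  return List::create(_["x"] = NumericVector(x.begin(), x.end()),
                      _["y"] = NumericVector(y.begin(), y.end()),
                      _["dx"] = NumericVector(dx.begin(), dx.end()),
                      _["dy"] = NumericVector(dy.begin(), dy.end()),
                      _["disp_x"] = ddx, _["disp_y"] = ddy,
                      _["rot"] = NumericVector(rot.begin(), rot.end()),
                      _["iters"] = used,
                      _["elapsed"] = used * dt_sub,
                      _["max_overlap"] = max_ov,
                      _["converged"] = max_ov <= overlap_tol);
}
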
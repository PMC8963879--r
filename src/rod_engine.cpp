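#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Overdamped 2D spherocylinder engine.
//
// Rods are segments of cylinder length L (pole-to-pole minus the two
// hemispherical caps) with diameter d; the segment runs from
// center - (L/2) u to center + (L/2) u with u = (cos theta, sin theta).
// Two rods interact when the minimal segment-segment distance drops below
// the mean of their diameters; repulsion is k * overlap^expo along the
// minimal-distance direction, applied at the midpoint of the closest points.
// ---------------------------------------------------------------------------

struct PairContact {
  int i, j;          // 0-based rod indices
  double cx, cy;     // contact point (midpoint of closest points)
  double fx, fy;     // force on rod i (rod j gets the opposite)
  double overlap;    // diameter-mean minus minimal distance
};

// Closest points between segments p1 +- h1*u1 and p2 +- h2*u2.
// Returns squared distance; c1/c2 receive the closest points.
static inline double seg_seg_closest(double p1x, double p1y, double u1x, double u1y, double h1,
                                     double p2x, double p2y, double u2x, double u2y, double h2,
                                     double &c1x, double &c1y, double &c2x, double &c2y) {
  // Parameterize as a1 + s*d1, s in [-h1, h1]; likewise t in [-h2, h2].
  const double rx = p1x - p2x, ry = p1y - p2y;
  const double a = 1.0;                    // |u1|^2
  const double b = u1x * u2x + u1y * u2y;  // u1.u2
  const double c = 1.0;                    // |u2|^2
  const double d = u1x * rx + u1y * ry;    // u1.r
  const double e = u2x * rx + u2y * ry;    // u2.r
  const double denom = a * c - b * b;      // >= 0

  double s, t;
  if (denom > 1e-12) {
    s = (b * e - c * d) / denom;
  } else {
    s = 0.0;  // parallel: pick s = 0, clamp below
  }
  if (s > h1) s = h1; else if (s < -h1) s = -h1;
  t = b * s + e;  // minimiser of distance for fixed s (c == 1)
  if (t > h2) {
    t = h2;
    s = b * t - d;
    if (s > h1) s = h1; else if (s < -h1) s = -h1;
  } else if (t < -h2) {
    t = -h2;
    s = b * t - d;
    if (s > h1) s = h1; else if (s < -h1) s = -h1;
  }
  c1x = p1x + s * u1x; c1y = p1y + s * u1y;
  c2x = p2x + t * u2x; c2y = p2y + t * u2y;
  const double dx = c1x - c2x, dy = c1y - c2y;
  return dx * dx + dy * dy;
}

// Pairwise contact forces with a uniform cell list.
// Appends contacts to `out`, accumulates forces/torques.
static void contact_forces_core(const std::vector<double> &x, const std::vector<double> &y,
                                const std::vector<double> &th, const std::vector<double> &len,
                                const std::vector<double> &diam, const std::vector<int> &ids,
                                double k, double expo,
                                std::vector<double> &fx, std::vector<double> &fy,
                                std::vector<double> &tq, double &max_overlap,
                                std::vector<PairContact> *out) {
  const int n = (int)x.size();
  if (n < 2) return;

  double cell = 0.0, xmin = x[0], xmax = x[0], ymin = y[0], ymax = y[0];
  for (int i = 0; i < n; ++i) {
    const double ext = len[i] + diam[i];
    if (ext > cell) cell = ext;
    if (x[i] < xmin) xmin = x[i];
    if (x[i] > xmax) xmax = x[i];
    if (y[i] < ymin) ymin = y[i];
    if (y[i] > ymax) ymax = y[i];
  }
  if (cell <= 0) cell = 1.0;
  const int ncx = std::max(1, (int)std::floor((xmax - xmin) / cell) + 1);
  const int ncy = std::max(1, (int)std::floor((ymax - ymin) / cell) + 1);
  std::vector<int> head((size_t)ncx * ncy, -1), nxt(n, -1), cix(n), ciy(n);
  for (int i = 0; i < n; ++i) {
    int gx = (int)std::floor((x[i] - xmin) / cell);
    int gy = (int)std::floor((y[i] - ymin) / cell);
    if (gx < 0) gx = 0; if (gx >= ncx) gx = ncx - 1;
    if (gy < 0) gy = 0; if (gy >= ncy) gy = ncy - 1;
    cix[i] = gx; ciy[i] = gy;
    const size_t ci = (size_t)gy * ncx + gx;
    nxt[i] = head[ci];
    head[ci] = i;
  }

  std::vector<double> ux(n), uy(n);
  for (int i = 0; i < n; ++i) { ux[i] = std::cos(th[i]); uy[i] = std::sin(th[i]); }

  for (int i = 0; i < n; ++i) {
    const double hi = 0.5 * len[i];
    for (int dgy = -1; dgy <= 1; ++dgy) {
      const int gy = ciy[i] + dgy;
      if (gy < 0 || gy >= ncy) continue;
      for (int dgx = -1; dgx <= 1; ++dgx) {
        const int gx = cix[i] + dgx;
        if (gx < 0 || gx >= ncx) continue;
        for (int j = head[(size_t)gy * ncx + gx]; j >= 0; j = nxt[j]) {
          if (j <= i) continue;
          const double dx = x[i] - x[j], dy = y[i] - y[j];
          const double cutoff = hi + 0.5 * len[j] + 0.5 * (diam[i] + diam[j]);
          if (dx * dx + dy * dy > cutoff * cutoff) continue;
          double c1x, c1y, c2x, c2y;
          const double d2 = seg_seg_closest(x[i], y[i], ux[i], uy[i], hi,
                                            x[j], y[j], ux[j], uy[j], 0.5 * len[j],
                                            c1x, c1y, c2x, c2y);
          const double sumrad = 0.5 * (diam[i] + diam[j]);
          if (d2 >= sumrad * sumrad) continue;

          // Contact manifold. A single closest-point contact is exact for
          // crossing rods, but nearly parallel rods touch along a line; a
          // lone midpoint force would lose the differential squeeze that
          // torques rods in a velocity gradient. For axes within ~45
          // degrees, sample the gap at both ends of the overlapping axial
          // interval instead (two half-stiffness contacts).
          const double b = ux[i] * ux[j] + uy[i] * uy[j];
          const double hj = 0.5 * len[j];
          double svals[2];
          int ncontact = 1;
          svals[0] = (c1x - x[i]) * ux[i] + (c1y - y[i]) * uy[i];
          if (std::fabs(b) > 0.7071) {
            const double e = ux[j] * (x[i] - x[j]) + uy[j] * (y[i] - y[j]);
            double sa = (-hj - e) / b, sb = (hj - e) / b;
            if (sa > sb) { const double tmp = sa; sa = sb; sb = tmp; }
            if (sa < -hi) sa = -hi;
            if (sb > hi) sb = hi;
            if (sb - sa > 0.25 * sumrad) {
              svals[0] = sa; svals[1] = sb; ncontact = 2;
            }
          }
          const double wgt = 1.0 / ncontact;
          for (int q = 0; q < ncontact; ++q) {
            const double ax = x[i] + svals[q] * ux[i];
            const double ay = y[i] + svals[q] * uy[i];
            double tt = (ax - x[j]) * ux[j] + (ay - y[j]) * uy[j];
            if (tt > hj) tt = hj; else if (tt < -hj) tt = -hj;
            const double bx = x[j] + tt * ux[j], by = y[j] + tt * uy[j];
            const double ddx = ax - bx, ddy = ay - by;
            const double dist = std::sqrt(ddx * ddx + ddy * ddy);
            const double overlap = sumrad - dist;
            if (overlap <= 0) continue;
            if (overlap > max_overlap) max_overlap = overlap;
            double nxv, nyv;
            if (dist > 1e-12) {
              nxv = ddx / dist; nyv = ddy / dist;
            } else {
              // coincident points (exactly collinear rods): deterministic
              // tie-break, perpendicular to the axis of the lower-id rod
              const int a2 = (ids[i] < ids[j]) ? i : j;
              nxv = -uy[a2]; nyv = ux[a2];
              if (a2 == j) { nxv = -nxv; nyv = -nyv; }
            }
            const double fmag = wgt * k * std::pow(overlap, expo);
            const double pfx = fmag * nxv, pfy = fmag * nyv;  // on rod i
            const double px = 0.5 * (ax + bx), py = 0.5 * (ay + by);
            fx[i] += pfx; fy[i] += pfy;
            fx[j] -= pfx; fy[j] -= pfy;
            tq[i] += (px - x[i]) * pfy - (py - y[i]) * pfx;
            tq[j] -= (px - x[j]) * pfy - (py - y[j]) * pfx;
            if (out) {
              PairContact pc; pc.i = i; pc.j = j; pc.cx = px; pc.cy = py;
              pc.fx = pfx; pc.fy = pfy; pc.overlap = overlap;
              out->push_back(pc);
            }
          }
        }
      }
    }
  }
}

// Inward repulsion from a fixed circular wall acting on protruding end caps.
static void wall_forces_core(const std::vector<double> &x, const std::vector<double> &y,
                             const std::vector<double> &th, const std::vector<double> &len,
                             const std::vector<double> &diam,
                             double wx, double wy, double wr, double kw, double expo,
                             std::vector<double> &fx, std::vector<double> &fy,
                             std::vector<double> &tq) {
  const int n = (int)x.size();
  for (int i = 0; i < n; ++i) {
    const double ux = std::cos(th[i]), uy = std::sin(th[i]);
    const double h = 0.5 * len[i];
    for (int e = -1; e <= 1; e += 2) {
      const double px = x[i] + e * h * ux, py = y[i] + e * h * uy;
      const double rx = px - wx, ry = py - wy;
      const double r = std::sqrt(rx * rx + ry * ry);
      const double prot = r + 0.5 * diam[i] - wr;
      if (prot <= 0 || r < 1e-12) continue;
      const double fmag = kw * std::pow(prot, expo);
      const double nfx = -fmag * rx / r, nfy = -fmag * ry / r;
      fx[i] += nfx; fy[i] += nfy;
      tq[i] += (px - x[i]) * nfy - (py - y[i]) * nfx;
    }
  }
}

// Division of over-threshold rods. Uses the R RNG (normal draws), so the
// stream is reproducible under set.seed(). The split point is drawn from
// N(0, (L*sd_frac)^2) truncated (by redraw) to |s| <= L*cap_frac, measured
// along the cylinder axis from the rod center. Children tile the parent's
// full spherocylinder extent, so their cylinder lengths sum to L - d.
static void divide_core(std::vector<double> &x, std::vector<double> &y,
                        std::vector<double> &th, std::vector<double> &len,
                        std::vector<double> &diam, std::vector<int> &strain,
                        std::vector<int> &ids, std::vector<int> &parent,
                        const NumericVector &Ldiv, const NumericVector &sd_frac,
                        const NumericVector &cap_frac, int &next_id) {
  const int n0 = (int)x.size();
  for (int i = 0; i < n0; ++i) {
    const int s = strain[i] - 1;  // strain ids are 1-based
    if (len[i] <= Ldiv[s]) continue;
    const double L = len[i], d = diam[i];
    const double cap = cap_frac[s] * L;
    double off;
    do {
      off = R::rnorm(0.0, sd_frac[s] * L);
    } while (std::fabs(off) > cap);
    const double ux = std::cos(th[i]), uy = std::sin(th[i]);
    const double la = off + 0.5 * (L - d);       // child A cylinder length
    const double lb = 0.5 * (L - d) - off;       // child B
    const double ca = 0.5 * (off - 0.5 * (L + d));  // centers along the axis
    const double cb = 0.5 * (off + 0.5 * (L + d));
    const double px = x[i], py = y[i];
    const int par = ids[i];
    // child A replaces the parent in place
    x[i] = px + ca * ux; y[i] = py + ca * uy; len[i] = la;
    ids[i] = next_id++; parent[i] = par;
    // child B appended
    x.push_back(px + cb * ux); y.push_back(py + cb * uy);
    th.push_back(th[i]); len.push_back(lb); diam.push_back(d);
    strain.push_back(strain[i]); ids.push_back(next_id++); parent.push_back(par);
  }
}

static std::vector<double> as_vec(const NumericVector &v) {
  return std::vector<double>(v.begin(), v.end());
}
static std::vector<int> as_ivec(const IntegerVector &v) {
  return std::vector<int>(v.begin(), v.end());
}

// [[Rcpp::export]]
List cpp_contact_forces(NumericVector x, NumericVector y, NumericVector theta,
                        NumericVector len, NumericVector diam, IntegerVector ids,
                        double k, double expo) {
  std::vector<double> xv = as_vec(x), yv = as_vec(y), tv = as_vec(theta),
      lv = as_vec(len), dv = as_vec(diam);
  std::vector<int> iv = as_ivec(ids);
  const int n = (int)xv.size();
  std::vector<double> fx(n, 0.0), fy(n, 0.0), tq(n, 0.0);
  std::vector<PairContact> contacts;
  double max_overlap = 0.0;
  contact_forces_core(xv, yv, tv, lv, dv, iv, k, expo, fx, fy, tq, max_overlap, &contacts);
  const int m = (int)contacts.size();
  IntegerVector pi(m), pj(m);
  NumericVector cx(m), cy(m), pfx(m), pfy(m), ov(m);
  for (int q = 0; q < m; ++q) {
    pi[q] = contacts[q].i + 1; pj[q] = contacts[q].j + 1;
    cx[q] = contacts[q].cx; cy[q] = contacts[q].cy;
    pfx[q] = contacts[q].fx; pfy[q] = contacts[q].fy;
    ov[q] = contacts[q].overlap;
  }
  return List::create(_["fx"] = NumericVector(fx.begin(), fx.end()),
                      _["fy"] = NumericVector(fy.begin(), fy.end()),
                      _["torque"] = NumericVector(tq.begin(), tq.end()),
                      _["pair_i"] = pi, _["pair_j"] = pj,
                      _["contact_x"] = cx, _["contact_y"] = cy,
                      _["force_x"] = pfx, _["force_y"] = pfy,
                      _["overlap"] = ov,
                      _["max_overlap"] = max_overlap);
}

// [[Rcpp::export]]
List cpp_wall_forces(NumericVector x, NumericVector y, NumericVector theta,
                     NumericVector len, NumericVector diam,
                     double wx, double wy, double wr, double kw, double expo) {
  std::vector<double> xv = as_vec(x), yv = as_vec(y), tv = as_vec(theta),
      lv = as_vec(len), dv = as_vec(diam);
  const int n = (int)xv.size();
  std::vector<double> fx(n, 0.0), fy(n, 0.0), tq(n, 0.0);
  wall_forces_core(xv, yv, tv, lv, dv, wx, wy, wr, kw, expo, fx, fy, tq);
  return List::create(_["fx"] = NumericVector(fx.begin(), fx.end()),
                      _["fy"] = NumericVector(fy.begin(), fy.end()),
                      _["torque"] = NumericVector(tq.begin(), tq.end()));
}

// [[Rcpp::export]]
List cpp_divide(NumericVector x, NumericVector y, NumericVector theta,
                NumericVector len, NumericVector diam, IntegerVector strain,
                IntegerVector ids, IntegerVector parent,
                NumericVector Ldiv, NumericVector sd_frac, NumericVector cap_frac,
                int next_id) {
  std::vector<double> xv = as_vec(x), yv = as_vec(y), tv = as_vec(theta),
      lv = as_vec(len), dv = as_vec(diam);
  std::vector<int> sv = as_ivec(strain), iv = as_ivec(ids), pv = as_ivec(parent);
  divide_core(xv, yv, tv, lv, dv, sv, iv, pv, Ldiv, sd_frac, cap_frac, next_id);
  return List::create(_["x"] = NumericVector(xv.begin(), xv.end()),
                      _["y"] = NumericVector(yv.begin(), yv.end()),
                      _["theta"] = NumericVector(tv.begin(), tv.end()),
                      _["length"] = NumericVector(lv.begin(), lv.end()),
                      _["diameter"] = NumericVector(dv.begin(), dv.end()),
                      _["strain_id"] = IntegerVector(sv.begin(), sv.end()),
                      _["id"] = IntegerVector(iv.begin(), iv.end()),
                      _["parent_id"] = IntegerVector(pv.begin(), pv.end()),
                      _["next_id"] = next_id);
}

// Advance the colony by n_steps of: grow -> divide -> forces -> overdamped
// update. Returns early (stopped = TRUE) once the rod count exceeds max_rods.
// [[Rcpp::export]]
List cpp_advance(NumericVector x, NumericVector y, NumericVector theta,
                 NumericVector len, NumericVector diam, IntegerVector strain,
                 IntegerVector ids, IntegerVector parent,
                 NumericVector Lambda, NumericVector Ldiv,
                 NumericVector sd_frac, NumericVector cap_frac,
                 double dt, double k, double expo, double zeta_t, double zeta_r,
                 double drag_ratio, double friction_gamma, double friction_mu,
                 bool has_wall, double wx, double wy, double wr, double kw,
                 int max_rods, int n_steps, double time0, int next_id) {
  std::vector<double> xv = as_vec(x), yv = as_vec(y), tv = as_vec(theta),
      lv = as_vec(len), dv = as_vec(diam);
  std::vector<int> sv = as_ivec(strain), iv = as_ivec(ids), pv = as_ivec(parent);

  double t = time0;
  bool stopped = false;
  double max_overlap = 0.0;
  int steps_done = 0;

  const int ns = Lambda.size();
  std::vector<double> gfac(ns);
  for (int s = 0; s < ns; ++s) gfac[s] = std::exp(Lambda[s] * dt);

  // previous-step velocities for the friction term (zero at entry)
  std::vector<double> vxv(xv.size(), 0.0), vyv(xv.size(), 0.0), omv(xv.size(), 0.0);

  for (int step = 0; step < n_steps; ++step) {
    const int n0 = (int)xv.size();
    for (int i = 0; i < n0; ++i) lv[i] *= gfac[sv[i] - 1];
    divide_core(xv, yv, tv, lv, dv, sv, iv, pv, Ldiv, sd_frac, cap_frac, next_id);
    const int n = (int)xv.size();
    if (n > max_rods) { stopped = true; break; }
    // children appended by division inherit zero velocity for this step
    vxv.resize(n, 0.0); vyv.resize(n, 0.0); omv.resize(n, 0.0);

    std::vector<double> fx(n, 0.0), fy(n, 0.0), tq(n, 0.0);
    double mo = 0.0;
    std::vector<PairContact> contacts;
    contact_forces_core(xv, yv, tv, lv, dv, iv, k, expo, fx, fy, tq, mo,
                        friction_gamma > 0 ? &contacts : nullptr);
    if (friction_gamma > 0) {
      for (const PairContact &pc : contacts) {
        const int i = pc.i, j = pc.j;
        const double fn = std::sqrt(pc.fx * pc.fx + pc.fy * pc.fy);
        if (fn <= 0) continue;
        const double nx = pc.fx / fn, ny = pc.fy / fn;
        const double rix = pc.cx - xv[i], riy = pc.cy - yv[i];
        const double rjx = pc.cx - xv[j], rjy = pc.cy - yv[j];
        const double vix = vxv[i] - omv[i] * riy, viy = vyv[i] + omv[i] * rix;
        const double vjx = vxv[j] - omv[j] * rjy, vjy = vyv[j] + omv[j] * rjx;
        double relx = vix - vjx, rely = viy - vjy;
        const double reln = relx * nx + rely * ny;
        relx -= reln * nx; rely -= reln * ny;
        double ftx = -friction_gamma * relx, fty = -friction_gamma * rely;
        const double ft = std::sqrt(ftx * ftx + fty * fty);
        const double cap = friction_mu * fn;
        if (ft > cap && ft > 0) { ftx *= cap / ft; fty *= cap / ft; }
        fx[i] += ftx; fy[i] += fty;
        fx[j] -= ftx; fy[j] -= fty;
        tq[i] += rix * fty - riy * ftx;
        tq[j] -= rjx * fty - rjy * ftx;
      }
    }
    if (has_wall) wall_forces_core(xv, yv, tv, lv, dv, wx, wy, wr, kw, expo, fx, fy, tq);
    if (mo > max_overlap) max_overlap = mo;

    for (int i = 0; i < n; ++i) {
      const double ext = lv[i] + dv[i];
      // anisotropic drag: the axial force component sees zeta_t * drag_ratio
      // (slender-body: sliding along the axis is easier than sideways)
      const double ax = std::cos(tv[i]), ay = std::sin(tv[i]);
      const double fpar = fx[i] * ax + fy[i] * ay;
      const double fperpx = fx[i] - fpar * ax, fperpy = fy[i] - fpar * ay;
      double dx = (fpar * ax * drag_ratio + fperpx) * dt / (zeta_t * ext);
      double dy = (fpar * ay * drag_ratio + fperpy) * dt / (zeta_t * ext);
      double dth = tq[i] * dt / (zeta_r * ext * ext * ext);
      // per-step displacement / rotation caps: a contact-chain overshoot
      // may never translate a rod further than a fraction of its diameter
      // (or rotate it more than the matching angle) in one step
      const double cap = 0.05 * dv[i];
      const double dr = std::sqrt(dx * dx + dy * dy);
      if (dr > cap) { dx *= cap / dr; dy *= cap / dr; }
      const double rot_cap = 0.1 * cap / dv[i];  // 0.005 rad at default cap
      if (dth > rot_cap) dth = rot_cap; else if (dth < -rot_cap) dth = -rot_cap;
      vxv[i] = dx / dt; vyv[i] = dy / dt; omv[i] = dth / dt;
      xv[i] += dx;
      yv[i] += dy;
      tv[i] += dth;
      // wrap to (-pi, pi]
      if (tv[i] <= -M_PI || tv[i] > M_PI) {
        tv[i] -= 2.0 * M_PI * std::floor((tv[i] + M_PI) / (2.0 * M_PI));
        if (tv[i] <= -M_PI) tv[i] += 2.0 * M_PI;
        if (tv[i] > M_PI) tv[i] -= 2.0 * M_PI;
      }
    }
    t += dt;
    ++steps_done;
  }

  return List::create(_["x"] = NumericVector(xv.begin(), xv.end()),
                      _["y"] = NumericVector(yv.begin(), yv.end()),
                      _["theta"] = NumericVector(tv.begin(), tv.end()),
                      _["length"] = NumericVector(lv.begin(), lv.end()),
                      _["diameter"] = NumericVector(dv.begin(), dv.end()),
                      _["strain_id"] = IntegerVector(sv.begin(), sv.end()),
                      _["id"] = IntegerVector(iv.begin(), iv.end()),
                      _["parent_id"] = IntegerVector(pv.begin(), pv.end()),
                      _["time"] = t, _["next_id"] = next_id,
                      _["stopped"] = stopped, _["steps_done"] = steps_done,
                      _["max_overlap"] = max_overlap);
}

// Minimal segment-segment distance (exported for seeding overlap checks).
// [[Rcpp::export]]
NumericVector cpp_min_pair_distance(NumericVector x, NumericVector y,
                                    NumericVector theta, NumericVector len) {
  const int n = x.size();
  std::vector<double> ux(n), uy(n);
  for (int i = 0; i < n; ++i) { ux[i] = std::cos(theta[i]); uy[i] = std::sin(theta[i]); }
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double c1x, c1y, c2x, c2y;
      const double d2 = seg_seg_closest(x[i], y[i], ux[i], uy[i], 0.5 * len[i],
                                        x[j], y[j], ux[j], uy[j], 0.5 * len[j],
                                        c1x, c1y, c2x, c2y);
      if (d2 < best) best = d2;
    }
  }
  return NumericVector::create(n >= 2 ? std::sqrt(best) : R_PosInf);
}

// Rasterize rod footprints onto a grid (1 = covered). Used for hole-area
// tracking and closure detection. Grid cell (ix, iy) covers
// [xmin + (ix-1)*h, xmin + ix*h) etc.; a cell is covered when its center
// lies within d/2 of a rod's axis segment.
// [[Rcpp::export]]
IntegerMatrix cpp_rasterize(NumericVector x, NumericVector y, NumericVector theta,
                            NumericVector len, NumericVector diam,
                            double xmin, double ymin, double h, int nx, int ny) {
  IntegerMatrix occ(nx, ny);
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    const double ux = std::cos(theta[i]), uy = std::sin(theta[i]);
    const double hl = 0.5 * len[i], rad = 0.5 * diam[i];
    const double ex = std::fabs(ux) * hl + rad, ey = std::fabs(uy) * hl + rad;
    int ix0 = (int)std::floor((x[i] - ex - xmin) / h), ix1 = (int)std::floor((x[i] + ex - xmin) / h);
    int iy0 = (int)std::floor((y[i] - ey - ymin) / h), iy1 = (int)std::floor((y[i] + ey - ymin) / h);
    if (ix0 < 0) ix0 = 0; if (ix1 >= nx) ix1 = nx - 1;
    if (iy0 < 0) iy0 = 0; if (iy1 >= ny) iy1 = ny - 1;
    for (int iy = iy0; iy <= iy1; ++iy) {
      const double cy = ymin + (iy + 0.5) * h;
      for (int ix = ix0; ix <= ix1; ++ix) {
        const double cx = xmin + (ix + 0.5) * h;
        // point-segment distance
        double s = (cx - x[i]) * ux + (cy - y[i]) * uy;
        if (s > hl) s = hl; else if (s < -hl) s = -hl;
        const double dx = cx - (x[i] + s * ux), dy = cy - (y[i] + s * uy);
        if (dx * dx + dy * dy <= rad * rad) occ(ix, iy) = 1;
      }
    }
  }
  return occ;
}

// Flood fill of the zero-region of occ containing (sx, sy) (1-based);
// returns the number of connected empty cells (4-connectivity), or 0 when
// the start cell is occupied.
// [[Rcpp::export]]
int cpp_flood_area(IntegerMatrix occ, int sx, int sy) {
  const int nx = occ.nrow(), ny = occ.ncol();
  int x0 = sx - 1, y0 = sy - 1;
  if (x0 < 0 || x0 >= nx || y0 < 0 || y0 >= ny) return 0;
  if (occ(x0, y0) != 0) return 0;
  std::vector<uint8_t> seen((size_t)nx * ny, 0);
  std::vector<int> stack;
  stack.push_back(y0 * nx + x0);
  seen[(size_t)y0 * nx + x0] = 1;
  int count = 0;
  while (!stack.empty()) {
    const int cur = stack.back(); stack.pop_back();
    const int cx = cur % nx, cy = cur / nx;
    ++count;
    const int dx[4] = {1, -1, 0, 0}, dy[4] = {0, 0, 1, -1};
    for (int q = 0; q < 4; ++q) {
      const int nxp = cx + dx[q], nyp = cy + dy[q];
      if (nxp < 0 || nxp >= nx || nyp < 0 || nyp >= ny) continue;
      const size_t idx = (size_t)nyp * nx + nxp;
      if (seen[idx] || occ(nxp, nyp) != 0) continue;
      seen[idx] = 1;
      stack.push_back((int)idx);
    }
  }
  return count;
}
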
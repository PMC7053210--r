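#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Axis-aligned chamber + two concentric spheres (ROI inside EPR shell).
// Coordinates are dimensionless chamber-lengths; one frame is the time unit.
struct Geom {
  double hx, hy, hz;      // chamber half-extents
  double cx, cy, cz;      // roi/epr center
  double r_roi, r_epr;
};

static const double T_MIN = 1e-12;  // reject immediate re-hits
static const double EPS  = 1e-9;    // post-event radial/axial nudge

// Region codes: 0 = FOV, 1 = EPR shell, 2 = ROI
static inline int classify_pt(const double* p, const Geom& g, bool epr) {
  double dx = p[0] - g.cx, dy = p[1] - g.cy, dz = p[2] - g.cz;
  double d2 = dx * dx + dy * dy + dz * dz;
  if (d2 < g.r_roi * g.r_roi) return 2;
  if (epr && d2 < g.r_epr * g.r_epr) return 1;
  return 0;
}

static inline double speed_mult(int region, double visc_epr, double visc_roi) {
  if (region == 2) return 1.0 - visc_roi;
  if (region == 1) return 1.0 - visc_epr;
  return 1.0;
}

// Surfaces: 0..5 chamber walls (+x,-x,+y,-y,+z,-z), 6 ROI sphere, 7 EPR sphere.
struct Hit {
  double t;
  int surface;
  bool any;
};

// Earliest crossing of segment p -> p + d with the active surfaces.
// Start point is assumed inside the chamber, so wall hits are exits only.
static Hit first_crossing(const double* p, const double* d, const Geom& g,
                          bool epr_enabled) {
  Hit best;
  best.t = 2.0;
  best.surface = -1;
  best.any = false;

  const double half[3] = {g.hx, g.hy, g.hz};
  for (int a = 0; a < 3; ++a) {
    if (d[a] > 0.0) {
      double t = (half[a] - p[a]) / d[a];
      if (t > T_MIN && t <= 1.0 && t < best.t) { best.t = t; best.surface = 2 * a; best.any = true; }
    } else if (d[a] < 0.0) {
      double t = (-half[a] - p[a]) / d[a];
      if (t > T_MIN && t <= 1.0 && t < best.t) { best.t = t; best.surface = 2 * a + 1; best.any = true; }
    }
  }

  // Spheres: first valid root of |q + t d|^2 = r^2 (q = p - center).
  double q[3] = {p[0] - g.cx, p[1] - g.cy, p[2] - g.cz};
  double a2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  if (a2 > 0.0) {
    double b = 2.0 * (q[0] * d[0] + q[1] * d[1] + q[2] * d[2]);
    double q2 = q[0] * q[0] + q[1] * q[1] + q[2] * q[2];
    int nsph = epr_enabled ? 2 : 1;
    for (int s = 0; s < nsph; ++s) {
      double r = (s == 0) ? g.r_roi : g.r_epr;
      double c = q2 - r * r;
      double disc = b * b - 4.0 * a2 * c;
      if (disc < 0.0) continue;
      double sq = std::sqrt(disc);
      double t1 = (-b - sq) / (2.0 * a2);
      double t2 = (-b + sq) / (2.0 * a2);
      double t = -1.0;
      if (t1 > T_MIN && t1 <= 1.0) t = t1;
      else if (t2 > T_MIN && t2 <= 1.0) t = t2;
      if (t > 0.0 && t < best.t) { best.t = t; best.surface = 6 + s; best.any = true; }
    }
  }
  return best;
}

// Rotate unit vector v toward unit vector u by at most `strength` radians,
// preserving the norm (the EPR "gravity-like" funnel turns, never rescales).
static void rotate_toward(double* v, const double* u, double strength) {
  double dot = v[0] * u[0] + v[1] * u[1] + v[2] * u[2];
  if (dot > 1.0) dot = 1.0;
  if (dot < -1.0) dot = -1.0;
  double theta = std::acos(dot);
  if (theta <= strength) { v[0] = u[0]; v[1] = u[1]; v[2] = u[2]; return; }
  double w[3] = {v[1] * u[2] - v[2] * u[1],
                 v[2] * u[0] - v[0] * u[2],
                 v[0] * u[1] - v[1] * u[0]};
  double wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (wn < 1e-12) {
    // v and u (anti)parallel: rotate in an arbitrary plane containing v
    double ax[3] = {1.0, 0.0, 0.0};
    if (std::fabs(v[0]) > 0.9) { ax[0] = 0.0; ax[1] = 1.0; }
    w[0] = v[1] * ax[2] - v[2] * ax[1];
    w[1] = v[2] * ax[0] - v[0] * ax[2];
    w[2] = v[0] * ax[1] - v[1] * ax[0];
    wn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
    if (wn < 1e-12) return;
  }
  for (int i = 0; i < 3; ++i) w[i] /= wn;
  double ca = std::cos(strength), sa = std::sin(strength);
  // Rodrigues with w perpendicular to v (w.v = 0)
  double wxv[3] = {w[1] * v[2] - w[2] * v[1],
                   w[2] * v[0] - w[0] * v[2],
                   w[0] * v[1] - w[1] * v[0]};
  double out[3];
  for (int i = 0; i < 3; ++i) out[i] = v[i] * ca + wxv[i] * sa;
  double n = std::sqrt(out[0] * out[0] + out[1] * out[1] + out[2] * out[2]);
  for (int i = 0; i < 3; ++i) v[i] = out[i] / n;
}

static Geom unpack_geom(const NumericVector& gv) {
  Geom g;
  g.hx = gv[0]; g.hy = gv[1]; g.hz = gv[2];
  g.cx = gv[3]; g.cy = gv[4]; g.cz = gv[5];
  g.r_roi = gv[6]; g.r_epr = gv[7];
  return g;
}

// One frame of kinetics for all active particles. Per particle, in index
// order: (a) EPR funnel rotation if starting the frame inside the shell,
// (b) displacement at base_speed x region multiplier, (c) continuous
// collision resolution with the remaining frame-time fraction rescaled by
// the new region's multiplier after every surface event. Escape coin-flips
// draw from R's RNG in particle order (one uniform per inside-shell hit).
//
// [[Rcpp::export]]
List motion_kernel(NumericMatrix pos_in, NumericMatrix dir_in,
                   IntegerVector status, LogicalVector entered_roi_in,
                   LogicalVector entered_epr_in, NumericVector geomv,
                   bool epr_enabled, bool responsive_mode,
                   double base_speed, double visc_epr, double visc_roi,
                   double escape_prob, double attraction) {
  Geom g = unpack_geom(geomv);
  int n = pos_in.nrow();
  NumericMatrix pos = clone(pos_in);
  NumericMatrix dir = clone(dir_in);
  LogicalVector entered_roi = clone(entered_roi_in);
  LogicalVector entered_epr = clone(entered_epr_in);
  int n_epr_hits = 0, n_epr_escapes = 0;
  bool out_of_bounds = false;

  const double half[3] = {g.hx, g.hy, g.hz};

  for (int i = 0; i < n; ++i) {
    if (status[i] != 1) continue;
    double p[3] = {pos(i, 0), pos(i, 1), pos(i, 2)};
    double v[3] = {dir(i, 0), dir(i, 1), dir(i, 2)};

    int region = classify_pt(p, g, epr_enabled);
    if (epr_enabled && region == 1 && attraction > 0.0) {
      double u[3] = {g.cx - p[0], g.cy - p[1], g.cz - p[2]};
      double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
      if (un > 1e-12) {
        for (int k = 0; k < 3; ++k) u[k] /= un;
        rotate_toward(v, u, attraction);
      }
    }

    double tau = 1.0;  // remaining fraction of the frame
    for (int iter = 0; iter < 256 && tau > 1e-12; ++iter) {
      region = classify_pt(p, g, epr_enabled);
      double len = base_speed * speed_mult(region, visc_epr, visc_roi) * tau;
      double d[3] = {v[0] * len, v[1] * len, v[2] * len};
      Hit h = first_crossing(p, d, g, epr_enabled);
      if (!h.any) {
        for (int k = 0; k < 3; ++k) p[k] += d[k];
        tau = 0.0;
        break;
      }
      double hp[3];
      for (int k = 0; k < 3; ++k) hp[k] = p[k] + h.t * d[k];
      tau *= (1.0 - h.t);

      if (h.surface < 6) {
        // chamber wall: specular reflection
        int a = h.surface / 2;
        double sgn = (h.surface % 2 == 0) ? 1.0 : -1.0;
        v[a] = -v[a];
        for (int k = 0; k < 3; ++k) p[k] = hp[k];
        p[a] = sgn * (half[a] - EPS);
      } else {
        // sphere event: radial unit normal at the hit point
        double r = (h.surface == 6) ? g.r_roi : g.r_epr;
        double nr[3] = {hp[0] - g.cx, hp[1] - g.cy, hp[2] - g.cz};
        double nn = std::sqrt(nr[0] * nr[0] + nr[1] * nr[1] + nr[2] * nr[2]);
        for (int k = 0; k < 3; ++k) nr[k] /= nn;
        if (h.surface == 6) {
          if (region == 2) {
            // inside the ROI: always reflected back (one-way trap)
            double dn = v[0] * nr[0] + v[1] * nr[1] + v[2] * nr[2];
            for (int k = 0; k < 3; ++k) v[k] -= 2.0 * dn * nr[k];
          } else {
            // uptake into the ROI: pass through, switch on if responsive
            entered_roi[i] = true;
          }
          p[0] = g.cx + nr[0] * (r - EPS);
          p[1] = g.cy + nr[1] * (r - EPS);
          p[2] = g.cz + nr[2] * (r - EPS);
        } else {
          if (region == 1) {
            // inside-shell hit on the EPR boundary: 50%-style escape rule
            ++n_epr_hits;
            double coin = R::unif_rand();
            if (coin < escape_prob) {
              ++n_epr_escapes;
              p[0] = g.cx + nr[0] * (r + EPS);
              p[1] = g.cy + nr[1] * (r + EPS);
              p[2] = g.cz + nr[2] * (r + EPS);
            } else {
              double dn = v[0] * nr[0] + v[1] * nr[1] + v[2] * nr[2];
              for (int k = 0; k < 3; ++k) v[k] -= 2.0 * dn * nr[k];
              p[0] = g.cx + nr[0] * (r - EPS);
              p[1] = g.cy + nr[1] * (r - EPS);
              p[2] = g.cz + nr[2] * (r - EPS);
            }
          } else {
            // entering the EPR zone from the FOV: pass through
            entered_epr[i] = true;
            p[0] = g.cx + nr[0] * (r - EPS);
            p[1] = g.cy + nr[1] * (r - EPS);
            p[2] = g.cz + nr[2] * (r - EPS);
          }
        }
      }
    }

    for (int k = 0; k < 3; ++k) {
      if (std::fabs(p[k]) > half[k] + 1e-6) out_of_bounds = true;
      pos(i, k) = p[k];
      dir(i, k) = v[k];
    }
  }

  (void)responsive_mode;  // emission is derived in R from entered_roi
  return List::create(_["pos"] = pos, _["dir"] = dir,
                      _["entered_roi"] = entered_roi,
                      _["entered_epr"] = entered_epr,
                      _["n_epr_hits"] = n_epr_hits,
                      _["n_epr_escapes"] = n_epr_escapes,
                      _["out_of_bounds"] = out_of_bounds);
}

// Single-segment continuous-collision query used by first_crossing() in R;
// shares the exact code path the motion kernel uses.
//
// [[Rcpp::export]]
List first_crossing_cpp(NumericVector start, NumericVector disp,
                        NumericVector geomv, bool epr_enabled) {
  Geom g = unpack_geom(geomv);
  double p[3] = {start[0], start[1], start[2]};
  double d[3] = {disp[0], disp[1], disp[2]};
  Hit h = first_crossing(p, d, g, epr_enabled);
  if (!h.any) return List::create(_["hit"] = false);
  double hp[3];
  for (int k = 0; k < 3; ++k) hp[k] = p[k] + h.t * d[k];
  double nr[3] = {0, 0, 0};
  bool entering = false;
  if (h.surface < 6) {
    int a = h.surface / 2;
    nr[a] = (h.surface % 2 == 0) ? 1.0 : -1.0;  // outward wall normal
    entering = false;                            // walls are always exits
  } else {
    double nn2 = 0.0;
    nr[0] = hp[0] - g.cx; nr[1] = hp[1] - g.cy; nr[2] = hp[2] - g.cz;
    nn2 = std::sqrt(nr[0] * nr[0] + nr[1] * nr[1] + nr[2] * nr[2]);
    for (int k = 0; k < 3; ++k) nr[k] /= nn2;
    entering = (d[0] * nr[0] + d[1] * nr[1] + d[2] * nr[2]) < 0.0;
  }
  return List::create(_["hit"] = true, _["t"] = h.t, _["surface"] = h.surface,
                      _["point"] = NumericVector::create(hp[0], hp[1], hp[2]),
                      _["normal"] = NumericVector::create(nr[0], nr[1], nr[2]),
                      _["entering"] = entering);
}
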
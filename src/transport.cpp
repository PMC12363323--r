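// Lagrangian droplet transport through the idealized curved nasal passage.
//
// State per droplet: position + velocity in the model frame (metres, m/s).
// Forces per unit mass: Stokes drag with Cunningham slip, gravity, and
// Saffman-Mei shear lift on the analytic parabolic profile. Integration is
// classical RK4 on the 6-dimensional state; small droplets (relaxation time
// well below the flow time-step) are sub-stepped so that h <= 2*tau, which
// keeps RK4 inside its stability region for the stiff drag term.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

struct Geometry {
  // dense uniform-in-s centerline table (planar curve in the x-z plane)
  std::vector<double> x_tab, z_tab, eps_tab, r_tab;
  int n;             // table size
  double vest_end, ant_end, naso_start;
  double end_c[3];   // outlet-plane point
  double end_t[3];   // outlet-plane outward normal (= end tangent)
  double t0[3];      // inlet tangent (nostril-plane normal)

  int region_of(double s) const {
    if (s >= naso_start) return 3;
    if (s >= ant_end) return 2;
    if (s >= vest_end) return 1;
    return 0;
  }
};

struct Local {
  double s, rho, r;     // arc fraction, centerline distance, tube radius
  double q[3], tg[3];   // nearest centerline point and unit tangent
  double erho[3];       // unit radial direction (zero if on centerline)
  double wall;          // signed wall distance (r - rho)
};

// signed axial coordinate of p relative to table node i (x-z plane)
inline double axial_excess(const Geometry& g, const double p[3], int i) {
  return (p[0] - g.x_tab[i]) * std::cos(g.eps_tab[i]) +
         (p[2] - g.z_tab[i]) * std::sin(g.eps_tab[i]);
}

// nearest-point projection onto the convex planar centerline; `hint` is the
// previous table index of the droplet (or -1 for a cold start)
inline void locate(const Geometry& g, const double p[3], Local& L,
                   int hint = -1) {
  const int nmax = g.n - 1;
  double d0 = axial_excess(g, p, 0);
  int lo, hi;
  if (d0 <= 0.0) {
    lo = hi = 0; // before the inlet: straight extension of the inlet axis
  } else if (axial_excess(g, p, nmax) >= 0.0) {
    lo = hi = nmax; // beyond the outlet plane
  } else if (hint >= 0) {
    // expand a bracket around the previous location
    int w = 2;
    lo = hint; hi = hint;
    while (lo > 0 && axial_excess(g, p, lo) <= 0.0) { lo -= w; w *= 2; }
    if (lo < 0) lo = 0;
    w = 2;
    while (hi < nmax && axial_excess(g, p, hi) >= 0.0) { hi += w; w *= 2; }
    if (hi > nmax) hi = nmax;
  } else {
    lo = 0; hi = nmax;
  }
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (axial_excess(g, p, mid) >= 0.0) lo = mid; else hi = mid;
  }
  double s, qx, qz, eps;
  if (lo == hi) {
    s = (double)lo / nmax;
    eps = g.eps_tab[lo];
    if (lo == 0 && d0 < 0.0) { // project onto the straight inlet extension
      qx = g.x_tab[0] + d0 * std::cos(eps);
      qz = g.z_tab[0] + d0 * std::sin(eps);
    } else {
      qx = g.x_tab[lo]; qz = g.z_tab[lo];
    }
  } else {
    double glo = axial_excess(g, p, lo), ghi = axial_excess(g, p, hi);
    double f = (glo - ghi > 1e-300) ? glo / (glo - ghi) : 0.5;
    s = (lo + f) / nmax;
    qx = g.x_tab[lo] + f * (g.x_tab[hi] - g.x_tab[lo]);
    qz = g.z_tab[lo] + f * (g.z_tab[hi] - g.z_tab[lo]);
    eps = g.eps_tab[lo] + f * (g.eps_tab[hi] - g.eps_tab[lo]);
  }
  L.s = s;
  L.q[0] = qx; L.q[1] = 0.0; L.q[2] = qz;
  L.tg[0] = std::cos(eps); L.tg[1] = 0.0; L.tg[2] = std::sin(eps);
  double dx = p[0] - L.q[0], dy = p[1] - L.q[1], dz = p[2] - L.q[2];
  L.rho = std::sqrt(dx * dx + dy * dy + dz * dz);
  if (L.rho > 1e-12) {
    L.erho[0] = dx / L.rho; L.erho[1] = dy / L.rho; L.erho[2] = dz / L.rho;
  } else {
    L.erho[0] = L.erho[1] = L.erho[2] = 0.0;
  }
  int i0 = (int)(s * nmax);
  if (i0 >= nmax) i0 = nmax - 1;
  double fr = s * nmax - i0;
  L.r = g.r_tab[i0] + fr * (g.r_tab[i0 + 1] - g.r_tab[i0]);
  L.wall = L.r - L.rho;
}

struct Fluid {
  double Q, rho_air, mu, nu;
};

struct Droplet {
  double D, rho_d, tau; // diameter (m), density, relaxation time
};

// air velocity and shear magnitude at an already-located point
inline void air_velocity(const Fluid& f, const Local& L, double u[3],
                         double& gamma) {
  if (L.wall > 0.0) {
    double umax = 2.0 * f.Q / (M_PI * L.r * L.r);
    double frac = 1.0 - (L.rho / L.r) * (L.rho / L.r);
    double um = umax * frac;
    u[0] = um * L.tg[0]; u[1] = um * L.tg[1]; u[2] = um * L.tg[2];
    gamma = -2.0 * umax * L.rho / (L.r * L.r); // du_axial/drho (negative)
  } else {
    u[0] = u[1] = u[2] = 0.0;
    gamma = 0.0;
  }
}

// total acceleration: drag + gravity + Saffman lift
inline void accel(const Geometry& g, const Fluid& f, const Droplet& d,
                  const double gvec[3], const double p[3], const double v[3],
                  double a[3], int& hint) {
  Local L;
  locate(g, p, L, hint);
  hint = (int)(L.s * (g.n - 1));
  double u[3], gamma;
  air_velocity(f, L, u, gamma);
  double sl[3] = {u[0] - v[0], u[1] - v[1], u[2] - v[2]};
  a[0] = sl[0] / d.tau + gvec[0];
  a[1] = sl[1] / d.tau + gvec[1];
  a[2] = sl[2] / d.tau + gvec[2];
  if (std::fabs(gamma) > 1e-8) {
    // Saffman (1965) lift in the Li-Ahmadi generalized form, K = 2.594;
    // deformation tensor of the local unidirectional shear has the single
    // off-diagonal pair (gamma/2) in the (tangent, radial) plane.
    const double K = 2.594;
    double denom = std::pow(gamma * gamma / 2.0, 0.25);
    double coef = 2.0 * K * std::sqrt(f.nu) * f.rho_air /
                  (d.rho_d * d.D * denom);
    double sl_t = sl[0] * L.tg[0] + sl[1] * L.tg[1] + sl[2] * L.tg[2];
    double sl_r = sl[0] * L.erho[0] + sl[1] * L.erho[1] + sl[2] * L.erho[2];
    double ct = coef * 0.5 * gamma * sl_r; // along tangent
    double cr = coef * 0.5 * gamma * sl_t; // along radial
    a[0] += ct * L.tg[0] + cr * L.erho[0];
    a[1] += ct * L.tg[1] + cr * L.erho[1];
    a[2] += ct * L.tg[2] + cr * L.erho[2];
  }
}

inline double outlet_excess(const Geometry& g, const double p[3]) {
  return (p[0] - g.end_c[0]) * g.end_t[0] + (p[1] - g.end_c[1]) * g.end_t[1] +
         (p[2] - g.end_c[2]) * g.end_t[2];
}

Geometry make_geometry(const List& geom) {
  Geometry g;
  g.x_tab = as<std::vector<double>>(geom["x_tab"]);
  g.z_tab = as<std::vector<double>>(geom["z_tab"]);
  g.eps_tab = as<std::vector<double>>(geom["eps_tab"]);
  g.r_tab = as<std::vector<double>>(geom["r_tab"]);
  g.n = (int)g.x_tab.size();
  g.vest_end = as<double>(geom["vestibule_end"]);
  g.ant_end = as<double>(geom["anterior_end"]);
  g.naso_start = as<double>(geom["naso_start"]);
  int e = g.n - 1;
  g.end_c[0] = g.x_tab[e]; g.end_c[1] = 0.0; g.end_c[2] = g.z_tab[e];
  g.end_t[0] = std::cos(g.eps_tab[e]); g.end_t[1] = 0.0;
  g.end_t[2] = std::sin(g.eps_tab[e]);
  g.t0[0] = std::cos(g.eps_tab[0]); g.t0[1] = 0.0;
  g.t0[2] = std::sin(g.eps_tab[0]);
  return g;
}

} // namespace

// [[Rcpp::export(name = ".track_cloud_cpp")]]
List track_cloud_cpp(NumericMatrix pos0, NumericMatrix vel0,
                     double diameter_m, double rho_d, double Cc,
                     List geom, double Q, double rho_air, double mu,
                     NumericVector gvec, double dt, double t_max,
                     int max_substeps = 256) {
  const int n = pos0.nrow();
  Geometry g = make_geometry(geom);
  Fluid f{Q, rho_air, mu, mu / rho_air};
  Droplet d{diameter_m, rho_d,
            rho_d * diameter_m * diameter_m * Cc / (18.0 * mu)};
  double gv[3] = {gvec[0], gvec[1], gvec[2]};

  int n_sub = (int)std::ceil(dt / (2.0 * d.tau));
  if (n_sub < 1) n_sub = 1;
  if (n_sub > max_substeps) n_sub = max_substeps;
  const double h = dt / n_sub;
  const long n_steps = (long)std::llround(t_max / dt);

  IntegerVector status(n), region(n, -1);
  NumericVector s_final(n), t_final(n);
  NumericMatrix pos_out(n, 3), vel_out(n, 3);

  for (int i = 0; i < n; ++i) {
    double p[3] = {pos0(i, 0), pos0(i, 1), pos0(i, 2)};
    double v[3] = {vel0(i, 0), vel0(i, 1), vel0(i, 2)};
    int st = 0; // 0 airborne, 1 trapped, 2 escaped outlet, 3 escaped nostril
    double t = 0.0;
    int hint = -1;
    Local L;
    locate(g, p, L, hint);
    hint = (int)(L.s * (g.n - 1));
    if (L.wall <= 0.0) { // started outside the lumen: immediately trapped
      st = 1;
    }
    for (long k = 0; k < n_steps && st == 0; ++k) {
      for (int sub = 0; sub < n_sub && st == 0; ++sub) {
        double p0[3] = {p[0], p[1], p[2]};
        double k1p[3], k1v[3], k2p[3], k2v[3], k3p[3], k3v[3], k4p[3], k4v[3];
        double pt[3], vt[3];
        // RK4 stages
        accel(g, f, d, gv, p, v, k1v, hint);
        k1p[0] = v[0]; k1p[1] = v[1]; k1p[2] = v[2];
        for (int c = 0; c < 3; ++c) {
          pt[c] = p[c] + 0.5 * h * k1p[c];
          vt[c] = v[c] + 0.5 * h * k1v[c];
        }
        accel(g, f, d, gv, pt, vt, k2v, hint);
        k2p[0] = vt[0]; k2p[1] = vt[1]; k2p[2] = vt[2];
        for (int c = 0; c < 3; ++c) {
          pt[c] = p[c] + 0.5 * h * k2p[c];
          vt[c] = v[c] + 0.5 * h * k2v[c];
        }
        accel(g, f, d, gv, pt, vt, k3v, hint);
        k3p[0] = vt[0]; k3p[1] = vt[1]; k3p[2] = vt[2];
        for (int c = 0; c < 3; ++c) {
          pt[c] = p[c] + h * k3p[c];
          vt[c] = v[c] + h * k3v[c];
        }
        accel(g, f, d, gv, pt, vt, k4v, hint);
        k4p[0] = vt[0]; k4p[1] = vt[1]; k4p[2] = vt[2];
        for (int c = 0; c < 3; ++c) {
          p[c] += h / 6.0 * (k1p[c] + 2.0 * k2p[c] + 2.0 * k3p[c] + k4p[c]);
          v[c] += h / 6.0 * (k1v[c] + 2.0 * k2v[c] + 2.0 * k3v[c] + k4v[c]);
        }
        t += h;
        if (!std::isfinite(p[0]) || !std::isfinite(p[1]) ||
            !std::isfinite(p[2]) || !std::isfinite(v[0]) ||
            !std::isfinite(v[1]) || !std::isfinite(v[2]))
          stop("droplet integration produced a non-finite state (droplet %d, t = %g s)",
               i + 1, t);
        // boundary bookkeeping
        if (outlet_excess(g, p) >= 0.0) {
          st = 2;
          locate(g, p, L, hint);
          break;
        }
        locate(g, p, L, hint);
        hint = (int)(L.s * (g.n - 1));
        if (L.wall <= 0.0) {
          // wall crossing inside this sub-step: bisect to 1e-6 m
          double a0 = 0.0, b0 = 1.0;
          double seg = std::sqrt((p[0] - p0[0]) * (p[0] - p0[0]) +
                                 (p[1] - p0[1]) * (p[1] - p0[1]) +
                                 (p[2] - p0[2]) * (p[2] - p0[2]));
          Local Lm;
          while (seg * (b0 - a0) > 1e-6) {
            double m = 0.5 * (a0 + b0);
            double pm[3] = {p0[0] + m * (p[0] - p0[0]),
                            p0[1] + m * (p[1] - p0[1]),
                            p0[2] + m * (p[2] - p0[2])};
            locate(g, pm, Lm, hint);
            if (Lm.wall <= 0.0) b0 = m; else a0 = m;
          }
          double m = b0;
          for (int c = 0; c < 3; ++c) p[c] = p0[c] + m * (p[c] - p0[c]);
          locate(g, p, L, hint);
          st = 1;
          break;
        }
        if (L.s <= 0.0 && axial_excess(g, p, 0) < -2e-3) {
          st = 3; // left through the nostril opening
          break;
        }
      }
    }
    if (st == 0) locate(g, p, L, hint);
    status[i] = st;
    s_final[i] = L.s;
    t_final[i] = t;
    if (st == 1) region[i] = g.region_of(L.s);
    pos_out(i, 0) = p[0]; pos_out(i, 1) = p[1]; pos_out(i, 2) = p[2];
    vel_out(i, 0) = v[0]; vel_out(i, 1) = v[1]; vel_out(i, 2) = v[2];
  }

  return List::create(_["status"] = status, _["region"] = region,
                      _["s_final"] = s_final, _["t_final"] = t_final,
                      _["position"] = pos_out, _["velocity"] = vel_out,
                      _["n_substeps"] = n_sub);
}

// [[Rcpp::export(name = ".locate_cpp")]]
List locate_cpp(NumericVector p_, List geom) {
  Geometry g = make_geometry(geom);
  double p[3] = {p_[0], p_[1], p_[2]};
  Local L;
  locate(g, p, L);
  return List::create(_["s"] = L.s, _["wall_distance"] = L.wall,
                      _["radial_distance"] = L.rho,
                      _["nearest"] = NumericVector::create(L.q[0], L.q[1], L.q[2]),
                      _["tangent"] = NumericVector::create(L.tg[0], L.tg[1], L.tg[2]));
}

// [[Rcpp::export(name = ".flow_velocity_cpp")]]
NumericVector flow_velocity_cpp(NumericVector p_, List geom, double Q,
                                double rho_air, double mu) {
  Geometry g = make_geometry(geom);
  Fluid f{Q, rho_air, mu, mu / rho_air};
  double p[3] = {p_[0], p_[1], p_[2]};
  Local L;
  locate(g, p, L);
  double u[3], gamma;
  air_velocity(f, L, u, gamma);
  return NumericVector::create(u[0], u[1], u[2]);
}

// [[Rcpp::export(name = ".accel_parts_cpp")]]
List accel_parts_cpp(NumericVector p_, NumericVector v_, double diameter_m,
                     double rho_d, double Cc, List geom, double Q,
                     double rho_air, double mu, NumericVector gvec) {
  Geometry g = make_geometry(geom);
  Fluid f{Q, rho_air, mu, mu / rho_air};
  Droplet d{diameter_m, rho_d,
            rho_d * diameter_m * diameter_m * Cc / (18.0 * mu)};
  double p[3] = {p_[0], p_[1], p_[2]};
  double v[3] = {v_[0], v_[1], v_[2]};
  Local L;
  locate(g, p, L);
  double u[3], gamma;
  air_velocity(f, L, u, gamma);
  double sl[3] = {u[0] - v[0], u[1] - v[1], u[2] - v[2]};
  NumericVector drag = NumericVector::create(sl[0] / d.tau, sl[1] / d.tau,
                                             sl[2] / d.tau);
  NumericVector saff(3);
  if (std::fabs(gamma) > 1e-8) {
    const double K = 2.594;
    double denom = std::pow(gamma * gamma / 2.0, 0.25);
    double coef = 2.0 * K * std::sqrt(f.nu) * f.rho_air /
                  (d.rho_d * d.D * denom);
    double sl_t = sl[0] * L.tg[0] + sl[1] * L.tg[1] + sl[2] * L.tg[2];
    double sl_r = sl[0] * L.erho[0] + sl[1] * L.erho[1] + sl[2] * L.erho[2];
    double ct = coef * 0.5 * gamma * sl_r;
    double cr = coef * 0.5 * gamma * sl_t;
    for (int c = 0; c < 3; ++c) saff[c] = ct * L.tg[c] + cr * L.erho[c];
  }
  return List::create(_["drag"] = drag, _["saffman"] = saff,
                      _["gravity"] = NumericVector::create(gvec[0], gvec[1], gvec[2]),
                      _["air_velocity"] = NumericVector::create(u[0], u[1], u[2]),
                      _["shear"] = gamma, _["tau"] = d.tau,
                      _["s"] = L.s, _["wall_distance"] = L.wall);
}
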
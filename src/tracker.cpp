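// Compiled Lagrangian tracking core: analytic/gridded field evaluation,
// ray-wall intersection against the axisymmetric region stack, exponential
// Stokes-drag integration, and the stick / bounce / detach wall physics.
// The R level carries the reference implementations of the same physics;
// tests assert consistency between the two routes on the event logs.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Geom {
  double zb[5];
  double rad[4];
  double screen_z, pitch, hw;
};

struct FieldSpec {
  int kind;                 // 1 poiseuille, 2 swirl, 3 grid-jet, 4 gridded
  double Q, S;
  Geom g;                   // analytic kinds reuse the geometry stack
  double phi;               // screen open fraction (jet kind)
  // gridded
  std::vector<double> xs, ys, zs, ux, uy, uz;
};

inline int region_index(const Geom& g, double z) {
  if (z <= g.zb[1]) return 0;
  if (z <= g.zb[2]) return 1;
  if (z <= g.zb[3]) return 2;
  return 3;
}

inline bool screen_open(const Geom& g, double x, double y) {
  double px = x / g.pitch; px -= std::floor(px);
  double py = y / g.pitch; py -= std::floor(py);
  return std::fabs(px - 0.5) < g.hw && std::fabs(py - 0.5) < g.hw;
}

inline double interp_axis(const std::vector<double>& ax, double v,
                          int& i0, double& t) {
  int n = (int)ax.size();
  if (v <= ax[0]) { i0 = 0; t = 0.0; return v; }
  if (v >= ax[n - 1]) { i0 = n - 2; t = 1.0; return v; }
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; (ax[mid] <= v ? lo : hi) = mid; }
  i0 = lo; t = (v - ax[lo]) / (ax[lo + 1] - ax[lo]);
  return v;
}

void eval_field(const FieldSpec& f, const double* p, double* u) {
  if (f.kind == 4) {
    int ix, iy, iz; double tx, ty, tz;
    interp_axis(f.xs, p[0], ix, tx);
    interp_axis(f.ys, p[1], iy, ty);
    interp_axis(f.zs, p[2], iz, tz);
    int nx = (int)f.xs.size(), ny = (int)f.ys.size();
    auto lin = [&](int a, int b, int c) { return a + nx * (b + ny * c); };
    for (int comp = 0; comp < 3; ++comp) {
      const std::vector<double>& A =
        comp == 0 ? f.ux : (comp == 1 ? f.uy : f.uz);
      double v00 = A[lin(ix, iy, iz)] * (1 - tx) + A[lin(ix + 1, iy, iz)] * tx;
      double v10 = A[lin(ix, iy + 1, iz)] * (1 - tx) + A[lin(ix + 1, iy + 1, iz)] * tx;
      double v01 = A[lin(ix, iy, iz + 1)] * (1 - tx) + A[lin(ix + 1, iy, iz + 1)] * tx;
      double v11 = A[lin(ix, iy + 1, iz + 1)] * (1 - tx) + A[lin(ix + 1, iy + 1, iz + 1)] * tx;
      u[comp] = (v00 * (1 - ty) + v10 * ty) * (1 - tz) +
                (v01 * (1 - ty) + v11 * ty) * tz;
    }
    return;
  }
  const Geom& g = f.g;
  double z = p[2];
  if (z < g.zb[0]) z = g.zb[0];
  if (z > g.zb[4]) z = g.zb[4];
  int idx = region_index(g, z);
  double R = g.rad[idx];
  double r2 = p[0] * p[0] + p[1] * p[1];
  double um = f.Q / (M_PI * R * R);
  double uz = 2.0 * um * std::max(0.0, 1.0 - r2 / (R * R));
  if (f.kind == 3 && z > g.zb[2] && z <= g.zb[3]) {
    uz *= screen_open(g, p[0], p[1]) ? 1.0 / f.phi : 0.0;
  }
  double uxv = 0.0, uyv = 0.0;
  if (f.S > 0.0) {
    double gz = z <= g.zb[2] ? 1.0
              : (z >= g.zb[3] ? 0.0 : (g.zb[3] - z) / (g.zb[3] - g.zb[2]));
    double r = std::sqrt(r2);
    if (r > 0.0) {
      double uth = f.S * um * (r / R) * gz;
      uxv = -uth * p[1] / r;
      uyv = uth * p[0] / r;
    }
  }
  u[0] = uxv; u[1] = uyv; u[2] = uz;
}

struct Hit {
  bool any;
  double t, p[3], n[3];
  int region;    // 0-based region index
  int kind;      // 1 wall, 2 grid_bar, 3 outlet
};

Hit intersect(const Geom& g, const double* p0, const double* p1) {
  Hit h; h.any = false;
  double d[3] = { p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2] };
  if (d[0] == 0 && d[1] == 0 && d[2] == 0) return h;
  const double eps = 1e-12;
  double t_a = 0.0;
  int reg = region_index(g, p0[2]);
  // start exactly on a boundary plane: take the region in travel direction
  for (int k = 1; k <= 3; ++k)
    if (std::fabs(p0[2] - g.zb[k]) < 1e-15)
      reg = d[2] > 0 ? k : k - 1;
  for (int iter = 0; iter < 8; ++iter) {
    double t_zb = 1.0; int plane = -1;
    if (d[2] != 0.0) {
      for (int k = 0; k < 5; ++k) {
        double tk = (g.zb[k] - p0[2]) / d[2];
        if (tk > t_a + eps && tk <= 1.0 && tk < t_zb - eps) { t_zb = tk; plane = k; }
      }
    }
    double R = g.rad[reg];
    double aa = d[0] * d[0] + d[1] * d[1];
    double t_rad = -1.0;
    if (aa > 0.0) {
      double bb = 2.0 * (p0[0] * d[0] + p0[1] * d[1]);
      double cc = p0[0] * p0[0] + p0[1] * p0[1] - R * R;
      double disc = bb * bb - 4.0 * aa * cc;
      if (disc >= 0.0) {
        double tr = (-bb + std::sqrt(disc)) / (2.0 * aa);
        double lim = plane >= 0 ? t_zb : 1.0;
        if (tr > t_a + eps && tr <= lim) t_rad = tr;
      }
    }
    if (t_rad > 0.0) {
      h.any = true; h.t = t_rad;
      for (int i = 0; i < 3; ++i) h.p[i] = p0[i] + t_rad * d[i];
      double rr = std::sqrt(h.p[0] * h.p[0] + h.p[1] * h.p[1]);
      h.n[0] = -h.p[0] / rr; h.n[1] = -h.p[1] / rr; h.n[2] = 0.0;
      h.region = reg; h.kind = 1;
      return h;
    }
    if (plane < 0) return h;
    double hp[3] = { p0[0] + t_zb * d[0], p0[1] + t_zb * d[1], p0[2] + t_zb * d[2] };
    bool up = d[2] > 0;
    if (plane == 0) {
      h.any = true; h.t = t_zb;
      for (int i = 0; i < 3; ++i) h.p[i] = hp[i];
      h.n[0] = 0; h.n[1] = 0; h.n[2] = 1;
      h.region = 0; h.kind = 1;
      return h;
    }
    if (plane == 4) {
      h.any = true; h.t = t_zb;
      for (int i = 0; i < 3; ++i) h.p[i] = hp[i];
      h.n[0] = 0; h.n[1] = 0; h.n[2] = -1;
      h.region = 3; h.kind = 3;
      return h;
    }
    double r_hit = std::sqrt(hp[0] * hp[0] + hp[1] * hp[1]);
    int nxt = up ? reg + 1 : reg - 1;
    if (g.rad[nxt] < g.rad[reg] - eps && r_hit > g.rad[nxt]) {
      h.any = true; h.t = t_zb;
      for (int i = 0; i < 3; ++i) h.p[i] = hp[i];
      h.n[0] = 0; h.n[1] = 0; h.n[2] = up ? -1 : 1;
      h.region = reg; h.kind = 1;
      return h;
    }
    if (std::fabs(g.zb[plane] - g.screen_z) < eps && !screen_open(g, hp[0], hp[1])) {
      h.any = true; h.t = t_zb;
      for (int i = 0; i < 3; ++i) h.p[i] = hp[i];
      h.n[0] = 0; h.n[1] = 0; h.n[2] = up ? -1 : 1;
      h.region = up ? nxt : reg;     // bar belongs to the grid zone
      h.kind = 2;
      return h;
    }
    t_a = t_zb;
    reg = nxt;
  }
  return h;
}

Geom geom_from_list(const List& gl) {
  Geom g;
  NumericVector zb = gl["zb"], rad = gl["rad"];
  for (int i = 0; i < 5; ++i) g.zb[i] = zb[i];
  for (int i = 0; i < 4; ++i) g.rad[i] = rad[i];
  g.screen_z = as<double>(gl["screen_z"]);
  g.pitch = as<double>(gl["screen_pitch"]);
  g.hw = as<double>(gl["screen_hw"]);
  return g;
}

FieldSpec field_from_list(const List& fl, const Geom& g) {
  FieldSpec f;
  f.kind = as<int>(fl["kind"]);
  f.g = g;
  if (f.kind == 4) {
    f.xs = as<std::vector<double> >(fl["xs"]);
    f.ys = as<std::vector<double> >(fl["ys"]);
    f.zs = as<std::vector<double> >(fl["zs"]);
    f.ux = as<std::vector<double> >(fl["ux"]);
    f.uy = as<std::vector<double> >(fl["uy"]);
    f.uz = as<std::vector<double> >(fl["uz"]);
    f.Q = 0; f.S = 0; f.phi = 1;
  } else {
    f.Q = as<double>(fl["Q"]);
    f.S = as<double>(fl["S"]);
    f.phi = as<double>(fl["open_fraction"]);
    NumericVector zb = fl["zb"], rad = fl["rad"];
    for (int i = 0; i < 5; ++i) f.g.zb[i] = zb[i];
    for (int i = 0; i < 4; ++i) f.g.rad[i] = rad[i];
    f.g.screen_z = as<double>(fl["screen_z"]);
    f.g.pitch = as<double>(fl["screen_pitch"]);
    f.g.hw = as<double>(fl["screen_hw"]);
  }
  return f;
}

} // namespace

// [[Rcpp::export]]
NumericMatrix cpp_field_velocity(List field, List geom, NumericMatrix pts) {
  Geom g = geom_from_list(geom);
  FieldSpec f = field_from_list(field, g);
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double p[3] = { pts(i, 0), pts(i, 1), pts(i, 2) }, u[3];
    eval_field(f, p, u);
    out(i, 0) = u[0]; out(i, 1) = u[1]; out(i, 2) = u[2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_intersect_path(NumericVector p0, NumericVector p1, List geom) {
  Geom g = geom_from_list(geom);
  double a[3] = { p0[0], p0[1], p0[2] }, b[3] = { p1[0], p1[1], p1[2] };
  Hit h = intersect(g, a, b);
  if (!h.any) return List::create(Named("any") = false);
  return List::create(
    Named("any") = true, Named("t") = h.t,
    Named("point") = NumericVector::create(h.p[0], h.p[1], h.p[2]),
    Named("normal") = NumericVector::create(h.n[0], h.n[1], h.n[2]),
    Named("region") = h.region + 1, Named("kind") = h.kind);
}

// [[Rcpp::export]]
List cpp_track(NumericMatrix init, List field, List geom, List phys,
               List control) {
  Geom g = geom_from_list(geom);
  FieldSpec f = field_from_list(field, g);
  const double mu = as<double>(phys["mu"]);
  const double rho = as<double>(phys["rho"]);
  const double rho_M = as<double>(phys["rho_M"]);
  const double rho_p = as<double>(phys["rho_p"]);
  const double Cu = as<double>(phys["Cu"]);
  const double fw = as<double>(phys["f"]);
  const double ks = as<double>(phys["ks"]);
  const double WA = as<double>(phys["WA"]);
  const double KC = as<double>(phys["KC"]);
  const double E_cap = as<double>(phys["E_cap"]);
  const double e_n = as<double>(phys["e_n"]);
  const double e_t = as<double>(phys["e_t"]);
  const double ds = as<double>(phys["ds"]);
  const double dt_tau_factor = as<double>(control["dt_tau_factor"]);
  const double dt_floor = as<double>(control["dt_floor"]);
  const double dt_cross_len = as<double>(control["dt_cross_len"]);
  const double dt_max = as<double>(control["dt_max"]);
  const double max_time = as<double>(control["max_time"]);
  const int max_impacts = as<int>(control["max_impacts"]);
  const double nudge = 1e-9;

  int n = init.nrow();
  NumericVector fin_x(n), fin_y(n), fin_z(n), fin_vx(n), fin_vy(n), fin_vz(n),
    fin_t(n);
  IntegerVector fin_status(n), fin_region(n), fin_nimp(n);

  std::vector<double> ev_t, ev_x, ev_y, ev_z, ev_vn, ev_vcr;
  std::vector<int> ev_id, ev_region, ev_kind, ev_out;
  std::vector<double> da_t, da_x, da_y, da_z, da_dp, da_us, da_FD, da_dm,
    da_am, da_sr, da_uR, da_uS;
  std::vector<int> da_id, da_region, da_out;

  for (int i = 0; i < n; ++i) {
    const int id = (int)init(i, 0);
    const double dp = init(i, 1);
    double x[3] = { init(i, 2), init(i, 3), init(i, 4) };
    double v[3] = { init(i, 5), init(i, 6), init(i, 7) };
    const double tau = rho_p * dp * dp * Cu / (18.0 * mu);
    const double Fst = 0.75 * M_PI * WA * dp;
    const double acr = std::cbrt(1.5 * M_PI * WA * dp * dp / KC);
    const double vcr = std::pow(2.0 * E_cap / dp, 10.0 / 7.0);
    const double uR = std::sqrt(Fst * acr / ((3.0 * fw / Cu) * (M_PI / 2.0) * rho * dp * dp * dp / 2.0));
    const double uS = std::sqrt(ks * Fst / ((3.0 * fw / Cu) * (M_PI / 2.0) * rho * dp * dp));
    double t = 0.0;
    int status = 0, nimp = 0, region = 0;

    while (t < max_time) {
      double u[3];
      eval_field(f, x, u);
      double sp2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double m = std::max(std::fabs(v[k]), std::fabs(u[k]));
        sp2 += m * m;
      }
      double speed = std::sqrt(sp2) + 1e-12;
      double dt = std::min(dt_max, dt_cross_len / speed);
      dt = std::min(dt, std::max(tau * dt_tau_factor, dt_floor));
      if (t + dt > max_time) dt = max_time - t;
      if (dt <= 0) break;
      double e = std::exp(-dt / tau);
      double vn3[3], xn[3];
      for (int k = 0; k < 3; ++k) {
        vn3[k] = u[k] + (v[k] - u[k]) * e;
        xn[k] = x[k] + u[k] * dt + (v[k] - u[k]) * tau * (1.0 - e);
      }
      Hit h = intersect(g, x, xn);
      if (!h.any) {
        for (int k = 0; k < 3; ++k) { x[k] = xn[k]; v[k] = vn3[k]; }
        t += dt;
        continue;
      }
      double eh = std::exp(-dt * h.t / tau);
      double vh[3];
      for (int k = 0; k < 3; ++k) vh[k] = u[k] + (v[k] - u[k]) * eh;
      t += dt * h.t;
      if (h.kind == 3) {          // outlet: particle emitted
        for (int k = 0; k < 3; ++k) { x[k] = h.p[k]; v[k] = vh[k]; }
        status = 2;
        break;
      }
      double vdotn = vh[0] * h.n[0] + vh[1] * h.n[1] + vh[2] * h.n[2];
      double vn = vdotn < 0 ? -vdotn : 0.0;   // grazing crossings count as vn = 0
      bool stick = vn <= vcr;
      ++nimp;
      ev_id.push_back(id); ev_t.push_back(t);
      ev_x.push_back(h.p[0]); ev_y.push_back(h.p[1]); ev_z.push_back(h.p[2]);
      ev_region.push_back(h.region + 1); ev_kind.push_back(h.kind);
      ev_vn.push_back(vn); ev_vcr.push_back(vcr);
      ev_out.push_back(stick ? 1 : 2);
      if (stick) {
        // single steady-flow detachment assessment at the stuck point
        double ps[3] = { h.p[0] + ds * h.n[0], h.p[1] + ds * h.n[1],
                         h.p[2] + ds * h.n[2] };
        double us3[3];
        eval_field(f, ps, us3);
        double udn = us3[0] * h.n[0] + us3[1] * h.n[1] + us3[2] * h.n[2];
        double ut2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double c = us3[k] - udn * h.n[k];
          ut2 += c * c;
        }
        double u_star = std::sqrt(mu * std::sqrt(ut2) / (rho_M * ds));
        double FD = (3.0 * fw / Cu) * (M_PI / 2.0) * dp * dp * rho * u_star * u_star;
        bool roll = FD * dp / 2.0 >= Fst * acr;
        bool slide = FD >= ks * Fst;
        int out = roll ? 1 : (slide ? 2 : 0);
        da_id.push_back(id); da_t.push_back(t);
        da_x.push_back(h.p[0]); da_y.push_back(h.p[1]); da_z.push_back(h.p[2]);
        da_region.push_back(h.region + 1); da_dp.push_back(dp);
        da_us.push_back(u_star); da_FD.push_back(FD);
        da_dm.push_back(FD * dp / 2.0); da_am.push_back(Fst * acr);
        da_sr.push_back(ks * Fst); da_uR.push_back(uR); da_uS.push_back(uS);
        da_out.push_back(out);
        if (out == 0) {
          status = 1; region = h.region + 1;
          for (int k = 0; k < 3; ++k) { x[k] = h.p[k]; v[k] = 0.0; }
          break;
        }
        // detached: restart from rest just off the wall
        for (int k = 0; k < 3; ++k) {
          x[k] = h.p[k] + nudge * h.n[k];
          v[k] = 0.0;
        }
      } else {
        double vt[3];
        for (int k = 0; k < 3; ++k) vt[k] = vh[k] - vdotn * h.n[k];
        for (int k = 0; k < 3; ++k) {
          v[k] = e_t * vt[k] + e_n * vn * h.n[k];
          x[k] = h.p[k] + nudge * h.n[k];
        }
      }
      if (nimp >= max_impacts) { status = 3; break; }
    }
    if (status == 0 && t >= max_time) status = 3;
    fin_x[i] = x[0]; fin_y[i] = x[1]; fin_z[i] = x[2];
    fin_vx[i] = v[0]; fin_vy[i] = v[1]; fin_vz[i] = v[2];
    fin_t[i] = t; fin_status[i] = status; fin_region[i] = region;
    fin_nimp[i] = nimp;
  }

  List states = List::create(
    Named("x") = fin_x, Named("y") = fin_y, Named("z") = fin_z,
    Named("vx") = fin_vx, Named("vy") = fin_vy, Named("vz") = fin_vz,
    Named("time") = fin_t, Named("status") = fin_status,
    Named("region") = fin_region, Named("n_impacts") = fin_nimp);
  List impacts = List::create(
    Named("id") = wrap(ev_id), Named("time") = wrap(ev_t),
    Named("x") = wrap(ev_x), Named("y") = wrap(ev_y), Named("z") = wrap(ev_z),
    Named("region") = wrap(ev_region), Named("kind") = wrap(ev_kind),
    Named("vn") = wrap(ev_vn), Named("vcr") = wrap(ev_vcr),
    Named("outcome") = wrap(ev_out));
  List detach = List::create(
    Named("id") = wrap(da_id), Named("time") = wrap(da_t),
    Named("x") = wrap(da_x), Named("y") = wrap(da_y), Named("z") = wrap(da_z),
    Named("region") = wrap(da_region), Named("dp") = wrap(da_dp),
    Named("u_star") = wrap(da_us), Named("FD") = wrap(da_FD),
    Named("drag_moment") = wrap(da_dm), Named("adhesion_moment") = wrap(da_am),
    Named("sliding_resistance") = wrap(da_sr),
    Named("uR_star") = wrap(da_uR), Named("uS_star") = wrap(da_uS),
    Named("outcome") = wrap(da_out));
  return List::create(Named("states") = states, Named("impacts") = impacts,
                      Named("detach") = detach);
}
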
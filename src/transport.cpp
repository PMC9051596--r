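// Condensed-history electron transport in water (class II: continuous loss by
// range inversion, explicit delta rays above a production threshold, Gaussian
// restricted-loss straggling, Highland small-angle multiple scattering).
// Geometry is water everywhere; the only surfaces that matter are the scored
// nucleus (entry records, in-nucleus deposit flags) and the world cylinder
// (escape). Lengths um, energies keV. RNG is R's stream (set.seed applies).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double MC2 = 510.99895;     // electron rest mass, keV
static const double X0_UM = 3.608e5;     // radiation length of water, um
// Moller hard-collision constant: 2 pi re^2 mc2 * n_e(water) per um
// = 2*pi*(2.818e-13 cm)^2 * 511 keV * 3.343e23 cm^-3 = 8.52e-3 keV/um
static const double MOLLER_K = 8.52e-3;

struct Nucleus {
  int type;            // 0 ellipsoid, 1 elliptic cylinder
  double ax, ay, az;   // half dimensions
  double cx, cy, cz;
  double rbound;       // bounding-sphere radius
};

struct World { double radius, height, cx, cy; };

struct Tables {
  std::vector<double> loge, logs, energy, range;
  double emin, emax;
  // stopping power, log-log linear
  double S(double e) const {
    if (e <= emin) e = emin;
    if (e >= emax) e = emax;
    double le = std::log(e);
    size_t i = seg(le);
    double t = (le - loge[i]) / (loge[i + 1] - loge[i]);
    return std::exp(logs[i] + t * (logs[i + 1] - logs[i]));
  }
  // CSDA range, piecewise linear in E (matches the R-side interpolation)
  double R(double e) const {
    if (e <= emin) return 0.0;
    if (e >= emax) e = emax;
    size_t i = segE(e);
    double t = (e - energy[i]) / (energy[i + 1] - energy[i]);
    return range[i] + t * (range[i + 1] - range[i]);
  }
  // exact inverse of R
  double Einv(double r) const {
    if (r <= 0) return emin;
    if (r >= range.back()) return emax;
    size_t lo = 0, hi = range.size() - 1;
    while (hi - lo > 1) { size_t m = (lo + hi) / 2; if (range[m] <= r) lo = m; else hi = m; }
    double t = (r - range[lo]) / (range[lo + 1] - range[lo]);
    return energy[lo] + t * (energy[lo + 1] - energy[lo]);
  }
 private:
  size_t seg(double le) const {
    size_t lo = 0, hi = loge.size() - 1;
    while (hi - lo > 1) { size_t m = (lo + hi) / 2; if (loge[m] <= le) lo = m; else hi = m; }
    return lo;
  }
  size_t segE(double e) const {
    size_t lo = 0, hi = energy.size() - 1;
    while (hi - lo > 1) { size_t m = (lo + hi) / 2; if (energy[m] <= e) lo = m; else hi = m; }
    return lo;
  }
};

static inline bool inside_nucleus(const Nucleus& n, double x, double y, double z) {
  double qx = (x - n.cx) / n.ax, qy = (y - n.cy) / n.ay, qz = (z - n.cz) / n.az;
  if (n.type == 0) return qx * qx + qy * qy + qz * qz <= 1.0 + 1e-12;
  return qx * qx + qy * qy <= 1.0 + 1e-12 && std::fabs(qz) <= 1.0 + 1e-12;
}

// segment [0, smax] intersection interval with the nucleus solid; returns
// true with [t0, t1] clipped to (-inf, inf) *not* clipped to the segment.
static bool nucleus_interval(const Nucleus& n, const double* p, const double* d,
                             double& t0, double& t1) {
  double qx = p[0] - n.cx, qy = p[1] - n.cy, qz = p[2] - n.cz;
  if (n.type == 0) {
    double dx = d[0] / n.ax, dy = d[1] / n.ay, dz = d[2] / n.az;
    double ex = qx / n.ax, ey = qy / n.ay, ez = qz / n.az;
    double A = dx * dx + dy * dy + dz * dz;
    double B = 2.0 * (ex * dx + ey * dy + ez * dz);
    double C = ex * ex + ey * ey + ez * ez - 1.0;
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0.0 || A <= 0.0) return false;
    double s = std::sqrt(disc);
    t0 = (-B - s) / (2.0 * A); t1 = (-B + s) / (2.0 * A);
    return true;
  }
  // elliptic cylinder: xy-ellipse interval intersect z-slab interval
  double e0, e1;
  double A = (d[0] / n.ax) * (d[0] / n.ax) + (d[1] / n.ay) * (d[1] / n.ay);
  double B = 2.0 * (qx * d[0] / (n.ax * n.ax) + qy * d[1] / (n.ay * n.ay));
  double C = (qx / n.ax) * (qx / n.ax) + (qy / n.ay) * (qy / n.ay) - 1.0;
  if (A < 1e-300) {
    if (C > 0.0) return false;
    e0 = -1e300; e1 = 1e300;
  } else {
    double disc = B * B - 4.0 * A * C;
    if (disc <= 0.0) return false;
    double s = std::sqrt(disc);
    e0 = (-B - s) / (2.0 * A); e1 = (-B + s) / (2.0 * A);
  }
  double z0, z1;
  if (std::fabs(d[2]) < 1e-300) {
    if (std::fabs(qz) > n.az) return false;
    z0 = -1e300; z1 = 1e300;
  } else {
    z0 = (-n.az - qz) / d[2]; z1 = (n.az - qz) / d[2];
    if (z0 > z1) std::swap(z0, z1);
  }
  t0 = std::max(e0, z0); t1 = std::min(e1, z1);
  return t1 > t0;
}

struct Settings {
  double cutoff, delta_thr, max_step;
  bool straggling, scattering;
  bool store_all;   // keep deposits outside the nucleus too
};

struct Sink {
  // deposits
  std::vector<double> dep_x, dep_y, dep_z, dep_amt, dep_step;
  std::vector<int> dep_in;
  // nucleus entries
  std::vector<double> ent_x, ent_y, ent_z, ent_ux, ent_uy, ent_uz, ent_e;
  double escaped = 0.0, deposited = 0.0, nucleus_energy = 0.0;

  void deposit(const Settings& st, double x, double y, double z, double amt,
               bool in_nuc, double step) {
    if (amt <= 0.0) return;
    deposited += amt;
    if (in_nuc) nucleus_energy += amt;
    if (st.store_all || in_nuc) {
      dep_x.push_back(x); dep_y.push_back(y); dep_z.push_back(z);
      dep_amt.push_back(amt); dep_in.push_back(in_nuc ? 1 : 0);
      dep_step.push_back(step);
    }
  }
};

struct P { double x, y, z, ux, uy, uz, e; };

static void rotate_dir(double* d, double thx, double thy) {
  // orthonormal basis perpendicular to d
  double ax = std::fabs(d[0]), ay = std::fabs(d[1]), az = std::fabs(d[2]);
  double ref[3] = {0, 0, 0};
  if (ax <= ay && ax <= az) ref[0] = 1; else if (ay <= az) ref[1] = 1; else ref[2] = 1;
  double u[3] = {d[1] * ref[2] - d[2] * ref[1],
                 d[2] * ref[0] - d[0] * ref[2],
                 d[0] * ref[1] - d[1] * ref[0]};
  double un = std::sqrt(u[0] * u[0] + u[1] * u[1] + u[2] * u[2]);
  for (int i = 0; i < 3; ++i) u[i] /= un;
  double v[3] = {d[1] * u[2] - d[2] * u[1],
                 d[2] * u[0] - d[0] * u[2],
                 d[0] * u[1] - d[1] * u[0]};
  double nd[3];
  for (int i = 0; i < 3; ++i) nd[i] = d[i] + thx * u[i] + thy * v[i];
  double nn = std::sqrt(nd[0] * nd[0] + nd[1] * nd[1] + nd[2] * nd[2]);
  for (int i = 0; i < 3; ++i) d[i] = nd[i] / nn;
}

static void transport_one(P start, const Nucleus& nuc, const World& world,
                          const Tables& tab, const Settings& st, Sink& sink) {
  std::vector<P> stack;
  stack.push_back(start);
  long guard = 0;

  while (!stack.empty()) {
    P part = stack.back(); stack.pop_back();
    double p[3] = {part.x, part.y, part.z};
    double d[3] = {part.ux, part.uy, part.uz};
    double E = part.e;
    if (E <= st.cutoff) {
      sink.deposit(st, p[0], p[1], p[2], E, inside_nucleus(nuc, p[0], p[1], p[2]), 0.0);
      continue;
    }
    bool inside = inside_nucleus(nuc, p[0], p[1], p[2]);

    while (E > st.cutoff) {
      if (++guard > 4000000L) stop("particle stuck: step budget exceeded");
      double Rres = tab.R(E);
      double step = std::min(st.max_step, 0.1 * Rres);
      if (step < 0.005) step = 0.005;
      // refine steps near (or inside) the nucleus so crossings are resolved
      double dxn = p[0] - nuc.cx, dyn = p[1] - nuc.cy, dzn = p[2] - nuc.cz;
      double dist = std::sqrt(dxn * dxn + dyn * dyn + dzn * dzn) - nuc.rbound;
      if (dist < step) step = std::min(step, std::max(dist, 0.35));
      bool last = false;
      if (step >= Rres) { step = Rres; last = true; }

      double Enew = last ? 0.0 : tab.Einv(Rres - step);
      if (Enew < 0.0) Enew = 0.0;
      double dE = E - Enew;

      // hard collisions (delta rays) above the production threshold
      double sumT = 0.0;
      std::vector<double> deltas;
      double beta2 = 1.0 - (MC2 / (E + MC2)) * (MC2 / (E + MC2));
      double Tmax = E / 2.0;
      if (Tmax > st.delta_thr && std::isfinite(st.delta_thr)) {
        double sig = MOLLER_K / beta2 * (1.0 / st.delta_thr - 1.0 / Tmax);
        int nd = (int) R::rpois(sig * step);
        for (int i = 0; i < nd; ++i) {
          double u = R::unif_rand();
          double T = 1.0 / (1.0 / st.delta_thr - u * (1.0 / st.delta_thr - 1.0 / Tmax));
          if (sumT + T > dE) break;  // keep total loss consistent with CSDA budget
          sumT += T; deltas.push_back(T);
        }
      }
      double soft = dE - sumT;
      if (st.straggling) {
        double tde = std::min(st.delta_thr, Tmax);
        if (!std::isfinite(tde)) tde = Tmax;
        double sg = std::sqrt(MOLLER_K * tde * step / beta2);
        soft += sg * R::norm_rand();
        if (soft < 0.0) soft = 0.0;
        if (soft > E - sumT) soft = E - sumT;
      }
      double loss = soft + sumT;

      // nucleus crossing bookkeeping along this segment
      double t0, t1;
      bool hit = nucleus_interval(nuc, p, d, t0, t1);
      if (!inside && hit && t0 > 1e-9 && t0 <= step) {
        double Ee = E - loss * (t0 / step);
        if (Ee > st.cutoff) {
          sink.ent_x.push_back(p[0] + t0 * d[0]);
          sink.ent_y.push_back(p[1] + t0 * d[1]);
          sink.ent_z.push_back(p[2] + t0 * d[2]);
          sink.ent_ux.push_back(d[0]); sink.ent_uy.push_back(d[1]); sink.ent_uz.push_back(d[2]);
          sink.ent_e.push_back(Ee);
        }
      }
      // state at the end of the segment
      if (hit) inside = (t0 <= step + 1e-9) && (t1 > step);
      else inside = false;

      double mid[3] = {p[0] + 0.5 * step * d[0], p[1] + 0.5 * step * d[1],
                       p[2] + 0.5 * step * d[2]};
      bool mid_in = inside_nucleus(nuc, mid[0], mid[1], mid[2]);
      sink.deposit(st, mid[0], mid[1], mid[2], soft, mid_in, step);

      for (double T : deltas) {
        // secondary direction from free-electron kinematics
        double ct = std::sqrt((T / E) * (E + 2.0 * MC2) / (T + 2.0 * MC2));
        if (ct > 1.0) ct = 1.0;
        double stheta = std::sqrt(1.0 - ct * ct);
        double phi = 2.0 * M_PI * R::unif_rand();
        double dd[3] = {d[0], d[1], d[2]};
        rotate_dir(dd, stheta * std::cos(phi) / std::max(ct, 0.1),
                   stheta * std::sin(phi) / std::max(ct, 0.1));
        if (T > st.cutoff) {
          stack.push_back({mid[0], mid[1], mid[2], dd[0], dd[1], dd[2], T});
        } else {
          sink.deposit(st, mid[0], mid[1], mid[2], T, mid_in, 0.0);
        }
      }

      E -= loss;
      p[0] += step * d[0]; p[1] += step * d[1]; p[2] += step * d[2];

      // world escape
      double wx = p[0] - world.cx, wy = p[1] - world.cy;
      if (wx * wx + wy * wy > world.radius * world.radius ||
          p[2] < 0.0 || p[2] > world.height) {
        sink.escaped += E;
        E = 0.0;
        break;
      }

      if (st.scattering && E > st.cutoff) {
        double Et = E + MC2;
        double pc = std::sqrt(Et * Et - MC2 * MC2);
        double pbeta = pc * pc / Et;  // keV
        double sr = step / X0_UM;
        double f = 1.0 + 0.038 * std::log(sr);
        if (f < 0.25) f = 0.25;
        double th0 = 13600.0 / pbeta * std::sqrt(sr) * f;
        rotate_dir(d, th0 * R::norm_rand(), th0 * R::norm_rand());
      }
    }
    if (E > 0.0)
      sink.deposit(st, p[0], p[1], p[2], E, inside_nucleus(nuc, p[0], p[1], p[2]), 0.0);
  }
}

static Nucleus make_nucleus(List nuc) {
  Nucleus n;
  n.type = as<int>(nuc["type"]);
  NumericVector h = nuc["half_axes"], c = nuc["center"];
  n.ax = h[0]; n.ay = h[1]; n.az = h[2];
  n.cx = c[0]; n.cy = c[1]; n.cz = c[2];
  n.rbound = std::max(h[0], std::max(h[1], h[2])) + 1e-6;
  return n;
}

static Tables make_tables(List tab) {
  Tables t;
  NumericVector e = tab["energy_keV"], s = tab["stopping_keV_per_um"];
  NumericVector re = tab["range_energy_keV"], r = tab["range_um"];
  for (int i = 0; i < e.size(); ++i) {
    t.loge.push_back(std::log(e[i])); t.logs.push_back(std::log(s[i]));
  }
  for (int i = 0; i < re.size(); ++i) {
    t.energy.push_back(re[i]); t.range.push_back(r[i]);
  }
  t.emin = e[0]; t.emax = e[e.size() - 1];
  return t;
}

static Settings make_settings(List s, bool store_all) {
  Settings st;
  st.cutoff = as<double>(s["tracking_cutoff_keV"]);
  st.delta_thr = as<double>(s["delta_production_threshold_keV"]);
  st.max_step = as<double>(s["max_step_um"]);
  st.straggling = as<bool>(s["straggling_enabled"]);
  st.scattering = as<bool>(s["scattering_enabled"]);
  st.store_all = store_all;
  return st;
}

// [[Rcpp::export]]
List cpp_transport_electron(NumericVector position, NumericVector direction,
                            double energy_keV, List nucleus, List world,
                            List tables, List settings, bool store_all = true) {
  RNGScope scope;
  Nucleus nuc = make_nucleus(nucleus);
  World w = {as<double>(world["radius"]), as<double>(world["height"]),
             as<double>(world["cx"]), as<double>(world["cy"])};
  Tables tab = make_tables(tables);
  Settings st = make_settings(settings, store_all);
  Sink sink;
  P start = {position[0], position[1], position[2],
             direction[0], direction[1], direction[2], energy_keV};
  transport_one(start, nuc, w, tab, st, sink);

  int nd = sink.dep_x.size(), ne = sink.ent_x.size();
  NumericMatrix dep(nd, 6), ent(ne, 7);
  for (int i = 0; i < nd; ++i) {
    dep(i, 0) = sink.dep_x[i]; dep(i, 1) = sink.dep_y[i]; dep(i, 2) = sink.dep_z[i];
    dep(i, 3) = sink.dep_amt[i]; dep(i, 4) = sink.dep_in[i]; dep(i, 5) = sink.dep_step[i];
  }
  for (int i = 0; i < ne; ++i) {
    ent(i, 0) = sink.ent_x[i]; ent(i, 1) = sink.ent_y[i]; ent(i, 2) = sink.ent_z[i];
    ent(i, 3) = sink.ent_ux[i]; ent(i, 4) = sink.ent_uy[i]; ent(i, 5) = sink.ent_uz[i];
    ent(i, 6) = sink.ent_e[i];
  }
  return List::create(_["deposits"] = dep, _["entries"] = ent,
                      _["escaped_keV"] = sink.escaped,
                      _["deposited_keV"] = sink.deposited,
                      _["nucleus_keV"] = sink.nucleus_energy);
}

// [[Rcpp::export]]
List cpp_run_campaign(NumericMatrix starts, NumericMatrix dirs, NumericVector energies,
                      List nucleus, List world, List tables, List settings) {
  RNGScope scope;
  Nucleus nuc = make_nucleus(nucleus);
  World w = {as<double>(world["radius"]), as<double>(world["height"]),
             as<double>(world["cx"]), as<double>(world["cy"])};
  Tables tab = make_tables(tables);
  Settings st = make_settings(settings, false);   // keep only in-nucleus deposits

  int n = energies.size();
  NumericVector ev_nuc(n), ev_dep(n), ev_esc(n);
  std::vector<double> ent_id, ent_x, ent_y, ent_z, ent_ux, ent_uy, ent_uz, ent_e;
  std::vector<double> dep_id, dep_x, dep_y, dep_z, dep_amt, dep_step;

  for (int i = 0; i < n; ++i) {
    Sink sink;
    P start = {starts(i, 0), starts(i, 1), starts(i, 2),
               dirs(i, 0), dirs(i, 1), dirs(i, 2), energies[i]};
    transport_one(start, nuc, w, tab, st, sink);
    ev_nuc[i] = sink.nucleus_energy; ev_dep[i] = sink.deposited; ev_esc[i] = sink.escaped;
    for (size_t j = 0; j < sink.ent_x.size(); ++j) {
      ent_id.push_back(i + 1);
      ent_x.push_back(sink.ent_x[j]); ent_y.push_back(sink.ent_y[j]);
      ent_z.push_back(sink.ent_z[j]); ent_ux.push_back(sink.ent_ux[j]);
      ent_uy.push_back(sink.ent_uy[j]); ent_uz.push_back(sink.ent_uz[j]);
      ent_e.push_back(sink.ent_e[j]);
    }
    for (size_t j = 0; j < sink.dep_x.size(); ++j) {
      dep_id.push_back(i + 1);
      dep_x.push_back(sink.dep_x[j]); dep_y.push_back(sink.dep_y[j]);
      dep_z.push_back(sink.dep_z[j]); dep_amt.push_back(sink.dep_amt[j]);
      dep_step.push_back(sink.dep_step[j]);
    }
  }
  auto colmat = [](std::vector<std::vector<double>*> cols) {
    int nr = cols[0]->size(), nc = cols.size();
    NumericMatrix m(nr, nc);
    for (int j = 0; j < nc; ++j)
      for (int i = 0; i < nr; ++i) m(i, j) = (*cols[j])[i];
    return m;
  };
  NumericMatrix entries = colmat({&ent_id, &ent_x, &ent_y, &ent_z,
                                  &ent_ux, &ent_uy, &ent_uz, &ent_e});
  NumericMatrix ndep = colmat({&dep_id, &dep_x, &dep_y, &dep_z, &dep_amt, &dep_step});
  return List::create(_["entries"] = entries, _["nucleus_deposits"] = ndep,
                      _["event_nucleus_keV"] = ev_nuc,
                      _["event_deposited_keV"] = ev_dep,
                      _["event_escaped_keV"] = ev_esc);
}
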
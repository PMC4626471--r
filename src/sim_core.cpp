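// Compiled core: analytic magnet field, generalized power-law viscosity,
// and the Lagrangian particle loop. All quantities SI.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

static const double MU0   = 4.0e-7 * M_PI;     // N/A^2
static const double KB_SI = 1.380649e-23;      // J/K

// ---------------------------------------------------------------------------
// Magnetics: exterior field of a uniformly magnetized rectangle via its
// equivalent surface current sheets. Returns B and the (symmetric, traceless)
// Jacobian: dBy/dx = dBx/dy and dBy/dy = -dBx/dx outside sources, so only two
// independent derivative components are accumulated.
// ---------------------------------------------------------------------------
struct FieldEval { double Bx, By, dBxdx, dBxdy; };

// vertical sheet x = x0, y in [ya, yb], out-of-plane current density K (A/m)
static inline void sheet_vertical(double x0, double ya, double yb, double K,
                                  double x, double y, FieldEval &f) {
  const double C  = MU0 * K / (2.0 * M_PI);
  const double v  = x - x0;
  const double u1 = ya - y, u2 = yb - y;
  const double R1 = v * v + u1 * u1, R2 = v * v + u2 * u2;
  f.Bx    += 0.5 * C * std::log(R2 / R1);
  f.By    += C * (std::atan(u2 / v) - std::atan(u1 / v));
  f.dBxdx += C * (v / R2 - v / R1);
  f.dBxdy += C * (u1 / R1 - u2 / R2);
}

// horizontal sheet y = y0, x in [xa, xb], density K
static inline void sheet_horizontal(double y0, double xa, double xb, double K,
                                    double x, double y, FieldEval &f) {
  const double C  = MU0 * K / (2.0 * M_PI);
  const double w  = y - y0;
  const double u1 = xa - x, u2 = xb - x;
  const double R1 = w * w + u1 * u1, R2 = w * w + u2 * u2;
  f.Bx    += -C * (std::atan(u2 / w) - std::atan(u1 / w));
  f.By    += 0.5 * C * std::log(R1 / R2);
  f.dBxdx += C * (w / R2 - w / R1);
  f.dBxdy += C * (u2 / R2 - u1 / R1);
}

// mg: x1, x2, y1, y2, Mx, My (magnetization components, A/m)
static inline FieldEval magnet_field(const double *mg, double x, double y) {
  FieldEval f = {0.0, 0.0, 0.0, 0.0};
  const double Mx = mg[4], My = mg[5];
  if (My != 0.0) {                 // magnetization along y: sheets on x-faces
    sheet_vertical(mg[0], mg[2], mg[3],  My, x, y, f);
    sheet_vertical(mg[1], mg[2], mg[3], -My, x, y, f);
  }
  if (Mx != 0.0) {                 // magnetization along x: sheets on y-faces
    sheet_horizontal(mg[3], mg[0], mg[1],  Mx, x, y, f);
    sheet_horizontal(mg[2], mg[0], mg[1], -Mx, x, y, f);
  }
  return f;
}

static inline FieldEval magnets_field(const NumericMatrix &mags,
                                      double x, double y) {
  FieldEval f = {0.0, 0.0, 0.0, 0.0};
  for (int k = 0; k < mags.nrow(); ++k) {
    double mg[6];
    for (int j = 0; j < 6; ++j) mg[j] = mags(k, j);
    FieldEval g = magnet_field(mg, x, y);
    f.Bx += g.Bx; f.By += g.By; f.dBxdx += g.dBxdx; f.dBxdy += g.dBxdy;
  }
  return f;
}

// [[Rcpp::export]]
NumericMatrix rect_field_cpp(NumericMatrix magnets, NumericMatrix pts) {
  const int n = pts.nrow();
  NumericMatrix out(n, 6);
  colnames(out) = CharacterVector::create("Bx", "By", "dBxdx", "dBxdy",
                                          "dBydx", "dBydy");
  for (int i = 0; i < n; ++i) {
    FieldEval f = magnets_field(magnets, pts(i, 0), pts(i, 1));
    out(i, 0) = f.Bx;    out(i, 1) = f.By;
    out(i, 2) = f.dBxdx; out(i, 3) = f.dBxdy;
    out(i, 4) = f.dBxdy; out(i, 5) = -f.dBxdx;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Generalised power-law viscosity eta(gamma_dot)
// vp: eta_inf, d_eta, a, b, n_inf, d_n, c, d, gdot_min
// ---------------------------------------------------------------------------
static inline double gpl_eta(double g, const double *vp) {
  double ag = std::fabs(g);
  if (ag < vp[8]) ag = vp[8];
  const double lam = vp[0] + vp[1] *
    std::exp(-(1.0 + ag / vp[2]) * std::exp(-vp[3] / ag));
  const double n = vp[4] - vp[5] *
    std::exp(-(1.0 + ag / vp[6]) * std::exp(-vp[7] / ag));
  return lam * std::pow(ag, n - 1.0);
}

// [[Rcpp::export]]
NumericVector gpl_eta_cpp(NumericVector gdot, NumericVector vp) {
  const int n = gdot.size();
  NumericVector out(n);
  double p[9];
  for (int j = 0; j < 9; ++j) p[j] = vp[j];
  for (int i = 0; i < n; ++i) out[i] = gpl_eta(gdot[i], p);
  return out;
}

// ---------------------------------------------------------------------------
// Per-particle RNG substream (splitmix64 + Box-Muller). Each particle owns an
// independent stream derived from the master seed and its index, so noise is
// stable under changes of the total particle count.
// ---------------------------------------------------------------------------
struct SubStream {
  uint64_t s;
  bool     have_spare;
  double   spare;
  void init(uint64_t master, uint64_t id) {
    // scramble the starting state so distinct particles land at widely
    // separated, pseudo-random points of the generator orbit (a plain
    // additive offset would make neighbouring streams shifted copies)
    uint64_t z = master + (id + 1) * 0x9E3779B97F4A7C15ULL;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    s = z ^ (z >> 31);
    have_spare = false;
    spare = 0.0;
    next(); next();
  }
  uint64_t next() {
    uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() {                  // (0, 1]
    return (next() >> 11) * (1.0 / 9007199254740992.0) +
           (0.5 / 9007199254740992.0);
  }
  double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1)), a = 2.0 * M_PI * u2;
    spare = r * std::sin(a);
    have_spare = true;
    return r * std::cos(a);
  }
};

static inline double mod_pos(double t, double p) {
  return t - p * std::floor(t / p);
}

static inline double polyval(const NumericVector &cf, double t) {
  double v = 0.0;
  for (int i = cf.size() - 1; i >= 0; --i) v = v * t + cf[i];
  return v;
}

// ---------------------------------------------------------------------------
// Particle transport loop.
//
// env list fields (all SI):
//   magnets (matrix), chi_b,
//   width, f0, f1, length, capture_wall (+1 upper wall / -1 lower wall),
//   wave_coef (poly, ascending), period,
//   m_grid, y_grid, u_tab (ny x nm), g_tab (ny x nm), profile_mode
//     (0 = plug everywhere, 1 = developed everywhere, 2 = plug upstream of
//      footprint then developed),
//   visc (9-vector),
//   r_core, r_h, D, rho_eff, K_cm, temperature,
//   n, inj_times, dt, t_max, seed, brownian (0/1),
//   integrator (0 overdamped / 1 inertial-exponential),
//   rec_idx (1-based particle indices to record, may be empty), rec_every.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List run_sim_cpp(List env) {
  NumericMatrix magnets = env["magnets"];
  const double chi_b = env["chi_b"];
  const double width = env["width"], f0 = env["f0"], f1 = env["f1"];
  const int    capture_wall = env["capture_wall"];
  NumericVector wave_coef = env["wave_coef"];
  const double period = env["period"];
  NumericVector m_grid = env["m_grid"], y_grid = env["y_grid"];
  NumericMatrix u_tab = env["u_tab"];
  const int profile_mode = env["profile_mode"];
  const double eta_drag = env["eta_drag"];   // particle-scale blood viscosity
  const double r_core = env["r_core"], r_h = env["r_h"], Dp = env["D"];
  const double rho_eff = env["rho_eff"], K_cm = env["K_cm"];
  const double temperature = env["temperature"];
  const int n = env["n"];
  NumericVector inj_times = env["inj_times"];
  const double dt = env["dt"], t_max = env["t_max"];
  const double seed_d = env["seed"];
  const bool brownian = as<int>(env["brownian"]) != 0;
  const int integrator = env["integrator"];
  IntegerVector rec_idx = env["rec_idx"];
  const int rec_every = env["rec_every"];

  // scramble the user seed so that consecutive seeds give unrelated
  // particle substreams (the per-particle init adds id * golden-gamma,
  // which an unmixed master would alias with seed + 1)
  uint64_t master = (uint64_t)seed_d + 0x243F6A8885A308D3ULL;
  master = (master ^ (master >> 30)) * 0xBF58476D1CE4E5B9ULL;
  master = (master ^ (master >> 27)) * 0x94D049BB133111EBULL;
  master ^= master >> 31;
  const double mu_b = MU0 * (1.0 + chi_b);
  const double hfac2 = 1.0 / (mu_b * mu_b);          // |H|^2 = |B|^2 * hfac2
  const double cm = 2.0 * M_PI * mu_b * r_core * r_core * r_core * K_cm;
  const int nsteps = (int)std::ceil(t_max / dt);
  const int n_inj = inj_times.size();
  const int ny = y_grid.size(), nm = m_grid.size();
  const double ylo = y_grid[0], ystep = y_grid[1] - y_grid[0];
  const double mlo = m_grid[0], mstep = m_grid[1] - m_grid[0];

  // state
  std::vector<double> px(n), py(n), pvx(n), pvy(n), t_cap(n, NA_REAL);
  std::vector<int> status(n, 0);       // 0 flowing, 2 captured, 3 passed, 4 upstream exit
  std::vector<int> entered(n, 0), inj_step(n);
  std::vector<SubStream> rng(n);

  // injection: even split across pulses, uniform transverse position within
  // (r_h, width - r_h), plug velocity at the injection instant
  for (int i = 0; i < n; ++i) {
    rng[i].init(master, (uint64_t)i);
    const int gi = (int)(((long long)i * n_inj) / n);  // pulse group
    const double ti = inj_times[gi];
    inj_step[i] = (int)std::llround(ti / dt);
    px[i] = 0.0;
    py[i] = r_h + rng[i].unif() * (width - 2.0 * r_h);
    pvx[i] = polyval(wave_coef, mod_pos(ti, period));
    pvy[i] = 0.0;
  }

  // trajectory recording
  const int n_rec = rec_idx.size();
  std::vector<int> rec_flag(n, -1);
  for (int k = 0; k < n_rec; ++k) rec_flag[rec_idx[k] - 1] = k;
  std::vector<double> rec;   // id, t, x, y, vx, vy, status
  if (n_rec > 0) rec.reserve((size_t)n_rec * (nsteps / rec_every + 2) * 7);

  double rep_max = 0.0;
  long long rep_viol = 0;
  const double drag3 = 3.0 * M_PI * eta_drag * Dp;    // = m_p / tau_p
  const double tau = rho_eff * Dp * Dp / (18.0 * eta_drag);
  const double sig = std::sqrt(2.0 * KB_SI * temperature / drag3 * dt);
  const double rep_fac = rho_eff * Dp / eta_drag;

  for (int s = 0; s < nsteps; ++s) {
    const double t = s * dt;
    const double tm = mod_pos(t, period);
    const double m_t = polyval(wave_coef, tm);        // mean inlet velocity
    // profile table column for this instant
    const double q = std::fabs(m_t);
    double qa = (q - mlo) / mstep;
    if (qa < 0.0) qa = 0.0;
    if (qa > nm - 1.001) qa = nm - 1.001;
    const int im = (int)qa;
    const double fm = qa - im;
    const double sgn = (m_t >= 0.0) ? 1.0 : -1.0;

    for (int i = 0; i < n; ++i) {
      if (status[i] != 0 || s < inj_step[i]) continue;

      // local fluid velocity (developed profile or plug)
      double ubx;
      bool developed = (profile_mode == 1) ||
                       (profile_mode == 2 && px[i] >= f0);
      if (developed) {
        double ya = (py[i] - ylo) / ystep;
        if (ya < 0.0) ya = 0.0;
        if (ya > ny - 1.001) ya = ny - 1.001;
        const int iy = (int)ya;
        const double fy = ya - iy;
        const double u0 = u_tab(iy, im)     + fy * (u_tab(iy + 1, im)     - u_tab(iy, im));
        const double u1 = u_tab(iy, im + 1) + fy * (u_tab(iy + 1, im + 1) - u_tab(iy, im + 1));
        ubx = sgn * (u0 + fm * (u1 - u0));
      } else {
        ubx = m_t;
      }

      // magnetophoretic force from grad |H|^2
      FieldEval f = magnets_field(magnets, px[i], py[i]);
      const double gH2x = 2.0 * (f.Bx * f.dBxdx + f.By * f.dBxdy) * hfac2;
      const double gH2y = 2.0 * (f.Bx * f.dBxdy - f.By * f.dBxdx) * hfac2;
      const double Fmx = cm * gH2x, Fmy = cm * gH2y;
      if (!std::isfinite(Fmx) || !std::isfinite(Fmy))
        stop("non-finite magnetophoretic force for particle %d at step %d",
             i + 1, s + 1);

      const double slx = Fmx / drag3, sly = Fmy / drag3;
      const double slip = std::sqrt(slx * slx + sly * sly);
      const double rep = rep_fac * slip;
      if (rep > rep_max) rep_max = rep;
      if (rep >= 1.0) ++rep_viol;

      const double ueqx = ubx + slx, ueqy = sly;
      if (integrator == 0) {                          // overdamped
        px[i] += ueqx * dt;
        py[i] += ueqy * dt;
        pvx[i] = ueqx;
        pvy[i] = ueqy;
      } else {                                        // inertial-exponential
        const double e = std::exp(-dt / tau);
        const double cxv = pvx[i] - ueqx, cyv = pvy[i] - ueqy;
        px[i] += ueqx * dt + tau * (1.0 - e) * cxv;
        py[i] += ueqy * dt + tau * (1.0 - e) * cyv;
        pvx[i] = ueqx + cxv * e;
        pvy[i] = ueqy + cyv * e;
      }
      if (brownian) {
        px[i] += sig * rng[i].norm();
        py[i] += sig * rng[i].norm();
      }

      // wall interaction: capture on the magnet-side wall inside the
      // footprint when F_M presses the particle into it, else specular
      // elastic reflection
      for (int guard = 0; guard < 8; ++guard) {
        if (py[i] < r_h) {
          if (capture_wall == -1 && px[i] >= f0 && px[i] <= f1 && Fmy < 0.0) {
            py[i] = r_h;
            status[i] = 2;
            t_cap[i] = t + dt;
          } else {
            py[i] = 2.0 * r_h - py[i];
            pvy[i] = -pvy[i];
            continue;
          }
        } else if (py[i] > width - r_h) {
          if (capture_wall == 1 && px[i] >= f0 && px[i] <= f1 && Fmy > 0.0) {
            py[i] = width - r_h;
            status[i] = 2;
            t_cap[i] = t + dt;
          } else {
            py[i] = 2.0 * (width - r_h) - py[i];
            pvy[i] = -pvy[i];
            continue;
          }
        }
        break;
      }

      if (status[i] == 0) {
        if (!entered[i] && px[i] >= f0) entered[i] = 1;
        if (px[i] > f1) status[i] = 3;                // left the section
        // transient wash-back below x = 0 re-enters with the next forward
        // phase; only far upstream drift retires a particle
        else if (px[i] < -0.05) status[i] = 4;
      } else if (status[i] == 2 && !entered[i]) {
        entered[i] = 1;                               // capture implies entry
      }

      if (rec_flag[i] >= 0 && (s % rec_every == 0 || status[i] != 0)) {
        rec.push_back(i + 1); rec.push_back(t + dt);
        rec.push_back(px[i]); rec.push_back(py[i]);
        rec.push_back(pvx[i]); rec.push_back(pvy[i]);
        rec.push_back(status[i]);
      }
    }
  }

  int n_entered = 0, n_captured = 0, n_passed = 0, n_flow = 0, n_up = 0;
  for (int i = 0; i < n; ++i) {
    if (entered[i]) ++n_entered;
    if (status[i] == 2) ++n_captured;
    else if (status[i] == 3) ++n_passed;
    else if (status[i] == 4) ++n_up;
    else if (status[i] == 0 && entered[i]) ++n_flow;
  }

  NumericMatrix traj(rec.size() / 7, 7);
  for (size_t k = 0; k < rec.size() / 7; ++k)
    for (int j = 0; j < 7; ++j) traj(k, j) = rec[7 * k + j];
  colnames(traj) = CharacterVector::create("particle", "t", "x", "y",
                                           "vx", "vy", "status");

  return List::create(
    _["status"] = wrap(status), _["entered"] = wrap(entered),
    _["x"] = wrap(px), _["y"] = wrap(py),
    _["vx"] = wrap(pvx), _["vy"] = wrap(pvy),
    _["capture_time"] = wrap(t_cap),
    _["n_entered"] = n_entered, _["n_captured"] = n_captured,
    _["n_passed"] = n_passed, _["n_flowing"] = n_flow,
    _["n_upstream"] = n_up,
    _["re_p_max"] = rep_max, _["re_p_violations"] = (double)rep_viol,
    _["trajectory"] = traj);
}
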
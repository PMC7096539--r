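#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// State layouts (fixed order, mirrored by R-side helpers):
//   full:     x1, y1, z, x2, y2, g     (6)
//   sub1:     x1, y1                   (2)   z frozen
//   sub2:     x2, y2                   (2)
//   fastslow: x1, y1, z                (3)
//   fullfast: x1, y1, x2, y2           (4)   z frozen (fast part of the full model,
//                                            0.002*g drive omitted as in the printed Jacobian)
enum SysCode { SYS_FULL = 1, SYS_SUB1 = 2, SYS_SUB2 = 3, SYS_FASTSLOW = 4, SYS_FULLFAST = 5 };

struct Pars {
  double a, b, c, d, Iext1, m, a2, tau2, Iext2, gamma, r, s, x0;
  int z_law;          // 0 = modified (septic term for z<0), 1 = original (linear for all z)
  double sub2_drive;  // effective drive for sub2 runs; NA -> Iext2
};

static Pars as_pars(const List& p) {
  Pars q;
  q.a = p["a"]; q.b = p["b"]; q.c = p["c"]; q.d = p["d"];
  q.Iext1 = p["Iext1"]; q.m = p["m"];
  q.a2 = p["a2"]; q.tau2 = p["tau2"]; q.Iext2 = p["Iext2"]; q.gamma = p["gamma"];
  q.r = p["r"]; q.s = p["s"]; q.x0 = p["x0"];
  q.z_law = as<int>(p["z_law"]);
  q.sub2_drive = as<double>(p["sub2_drive"]);
  return q;
}

// f1 with x2 coupling (full model); the x1 >= 0 branch slope depends on x2.
static inline double f1_full(double x1, double x2, double z, const Pars& p) {
  if (x1 < 0) return p.a * x1 * x1 * x1 - p.b * x1 * x1;
  double zz = z - 4.0;
  return -(p.m - x2 + 0.6 * zz * zz) * x1;
}

// f1 without x2 coupling (subsystem 1 / fast-slow subsystem).
static inline double f1_sub(double x1, double z, const Pars& p) {
  if (x1 < 0) return p.a * x1 * x1 * x1 - p.b * x1 * x1;
  double zz = z - 4.0;
  return -(p.m + 0.6 * zz * zz) * x1;
}

static inline double f2v(double x2, const Pars& p) {
  return (x2 < -0.25) ? 0.0 : p.a2 * (x2 + 0.25);
}

// Slow permittivity dynamics; modified law adds -0.1*z^7 inside the bracket for z < 0.
static inline double zdot(double x1, double z, const Pars& p) {
  double bracket = p.s * (x1 - p.x0) - z;
  if (p.z_law == 0 && z < 0) bracket -= 0.1 * std::pow(z, 7);
  return p.r * bracket;
}

static void rhs_core(int sys, const double* y, double* dy, const Pars& p,
                     double z_frozen, bool freeze_z) {
  switch (sys) {
  case SYS_FULL: {
    double x1 = y[0], y1 = y[1], z = y[2], x2 = y[3], y2 = y[4], g = y[5];
    if (freeze_z) z = z_frozen;
    dy[0] = y1 - f1_full(x1, x2, z, p) - z + p.Iext1;
    dy[1] = p.c - p.d * x1 * x1 - y1;
    dy[2] = freeze_z ? 0.0 : zdot(x1, z, p);
    dy[3] = -y2 + x2 - x2 * x2 * x2 + p.Iext2 + 0.002 * g - 0.3 * (z - 3.5);
    dy[4] = (-y2 + f2v(x2, p)) / p.tau2;
    dy[5] = x1 - p.gamma * g;
    break;
  }
  case SYS_SUB1: {
    double x1 = y[0], y1 = y[1];
    double z = z_frozen;
    dy[0] = y1 - f1_sub(x1, z, p) - z + p.Iext1;
    dy[1] = p.c - p.d * x1 * x1 - y1;
    break;
  }
  case SYS_SUB2: {
    double x2 = y[0], y2 = y[1];
    double drive = R_IsNA(p.sub2_drive) ? p.Iext2 : p.sub2_drive;
    dy[0] = -y2 + x2 - x2 * x2 * x2 + drive;
    dy[1] = (-y2 + f2v(x2, p)) / p.tau2;
    break;
  }
  case SYS_FASTSLOW: {
    double x1 = y[0], y1 = y[1], z = y[2];
    if (freeze_z) z = z_frozen;
    dy[0] = y1 - f1_sub(x1, z, p) - z + p.Iext1;
    dy[1] = p.c - p.d * x1 * x1 - y1;
    dy[2] = freeze_z ? 0.0 : zdot(x1, z, p);
    break;
  }
  case SYS_FULLFAST: {
    double x1 = y[0], y1 = y[1], x2 = y[2], y2 = y[3];
    double z = z_frozen;
    dy[0] = y1 - f1_full(x1, x2, z, p) - z + p.Iext1;
    dy[1] = p.c - p.d * x1 * x1 - y1;
    dy[2] = -y2 + x2 - x2 * x2 * x2 + p.Iext2 - 0.3 * (z - 3.5);
    dy[3] = (-y2 + f2v(x2, p)) / p.tau2;
    break;
  }
  default:
    stop("unknown system code");
  }
}

// [[Rcpp::export(name = ".rhs_cpp")]]
NumericVector rhs_cpp(int sys, NumericVector state, List pars,
                      double z_frozen, bool freeze_z) {
  Pars p = as_pars(pars);
  int n = state.size();
  NumericVector out(n);
  rhs_core(sys, REAL(state), REAL(out), p, z_frozen, freeze_z);
  return out;
}

static inline bool bad_state(const double* y, int n, double guard) {
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(y[i]) || std::fabs(y[i]) > guard) return true;
  return false;
}

// Classical fixed-step 4th-order Runge-Kutta.  Records every `record_every`
// steps (plus the initial and final states).  On overflow the trajectory is
// truncated and flagged rather than raising.
// [[Rcpp::export(name = ".rk4_cpp")]]
List rk4_cpp(int sys, NumericVector y0, double t0, double t1, double dt,
             List pars, double z_frozen, bool freeze_z,
             int record_every, double guard) {
  Pars p = as_pars(pars);
  const int n = y0.size();
  if (t1 <= t0) stop("invalid time span");
  long nsteps = (long)std::ceil((t1 - t0) / dt - 1e-12);
  double h = (t1 - t0) / (double)nsteps;
  long nrec = nsteps / record_every + 2;

  NumericMatrix states(nrec, n);
  NumericVector times(nrec);
  std::vector<double> y(n), k1(n), k2(n), k3(n), k4(n), tmp(n);
  for (int i = 0; i < n; ++i) y[i] = y0[i];
  if (bad_state(&y[0], n, guard)) stop("non-finite initial state");

  long irec = 0;
  times[irec] = t0;
  for (int j = 0; j < n; ++j) states(irec, j) = y[j];
  ++irec;

  bool diverged = false;
  double t = t0;
  for (long step = 1; step <= nsteps; ++step) {
    rhs_core(sys, &y[0], &k1[0], p, z_frozen, freeze_z);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * h * k1[j];
    rhs_core(sys, &tmp[0], &k2[0], p, z_frozen, freeze_z);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + 0.5 * h * k2[j];
    rhs_core(sys, &tmp[0], &k3[0], p, z_frozen, freeze_z);
    for (int j = 0; j < n; ++j) tmp[j] = y[j] + h * k3[j];
    rhs_core(sys, &tmp[0], &k4[0], p, z_frozen, freeze_z);
    for (int j = 0; j < n; ++j)
      y[j] += h / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);
    t = t0 + step * h;
    if (bad_state(&y[0], n, guard)) { diverged = true; break; }
    if (step % record_every == 0 || step == nsteps) {
      times[irec] = t;
      for (int j = 0; j < n; ++j) states(irec, j) = y[j];
      ++irec;
    }
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["n_recorded"] = (double)irec, _["diverged"] = diverged,
                      _["dt"] = h);
}

// Euler-Maruyama with additive Gaussian white noise on selected components.
// With all noise_sd zero this is plain forward Euler.  Uses R's RNG so that
// set.seed() on the R side makes runs reproducible.
// [[Rcpp::export(name = ".em_cpp")]]
List em_cpp(int sys, NumericVector y0, double t0, double t1, double dt,
            List pars, NumericVector noise_sd, double z_frozen, bool freeze_z,
            int record_every, double guard) {
  Pars p = as_pars(pars);
  const int n = y0.size();
  if (noise_sd.size() != n) stop("noise_sd length must match state dimension");
  if (t1 <= t0) stop("invalid time span");
  long nsteps = (long)std::ceil((t1 - t0) / dt - 1e-12);
  double h = (t1 - t0) / (double)nsteps;
  double sqh = std::sqrt(h);
  long nrec = nsteps / record_every + 2;

  NumericMatrix states(nrec, n);
  NumericVector times(nrec);
  std::vector<double> y(n), k1(n);
  bool any_noise[64];
  for (int j = 0; j < n; ++j) { y[j] = y0[j]; any_noise[j] = noise_sd[j] > 0; }
  if (bad_state(&y[0], n, guard)) stop("non-finite initial state");

  RNGScope scope;
  long irec = 0;
  times[irec] = t0;
  for (int j = 0; j < n; ++j) states(irec, j) = y[j];
  ++irec;

  bool diverged = false;
  for (long step = 1; step <= nsteps; ++step) {
    rhs_core(sys, &y[0], &k1[0], p, z_frozen, freeze_z);
    for (int j = 0; j < n; ++j) {
      y[j] += h * k1[j];
      if (any_noise[j]) y[j] += sqh * noise_sd[j] * norm_rand();
    }
    if (bad_state(&y[0], n, guard)) { diverged = true; break; }
    if (step % record_every == 0 || step == nsteps) {
      times[irec] = t0 + step * h;
      for (int j = 0; j < n; ++j) states(irec, j) = y[j];
      ++irec;
    }
  }
  return List::create(_["times"] = times, _["states"] = states,
                      _["n_recorded"] = (double)irec, _["diverged"] = diverged,
                      _["dt"] = h);
}
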
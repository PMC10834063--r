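#include <Rcpp.h>
using namespace Rcpp;

// Classical squid-axon gating rates (voltage in mV, rates in 1/ms).
static inline double an_(double v) {
  double x = v + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;  // limit of 0.01 x / (1 - exp(-x/10))
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bn_(double v) { return 0.125 * std::exp(-(v + 65.0) / 80.0); }
static inline double am_(double v) {
  double x = v + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double bm_(double v) { return 4.0 * std::exp(-(v + 65.0) / 18.0); }
static inline double ah_(double v) { return 0.07 * std::exp(-(v + 65.0) / 20.0); }
static inline double bh_(double v) { return 1.0 / (1.0 + std::exp(-(v + 35.0) / 10.0)); }

struct HHP {
  double Cm, gK, gNa, gL, VK, VNa, VL;
};

static inline void hh_rhs(const double* s, double I, const HHP& p, double* ds) {
  double v = s[0], n = s[1], m = s[2], h = s[3];
  double iK = p.gK * n * n * n * n * (v - p.VK);
  double iNa = p.gNa * m * m * m * h * (v - p.VNa);
  double iL = p.gL * (v - p.VL);
  ds[0] = (I - iK - iNa - iL) / p.Cm;
  ds[1] = an_(v) * (1.0 - n) - bn_(v) * n;
  ds[2] = am_(v) * (1.0 - m) - bm_(v) * m;
  ds[3] = ah_(v) * (1.0 - h) - bh_(v) * h;
}

// Linear interpolation of the stimulus (uniform grid t0 + k*dt_s), zero
// outside the record.
static inline double stim_at(double t, const NumericVector& si,
                             double t0, double dt_s) {
  double u = (t - t0) / dt_s;
  if (u < 0.0) return 0.0;
  int k = (int)std::floor(u);
  int n = si.size();
  if (k >= n - 1) return (u <= (double)(n - 1) + 1e-9 && k == n - 1) ? si[n - 1] : 0.0;
  double w = u - k;
  return si[k] * (1.0 - w) + si[k + 1] * w;
}

// [[Rcpp::export(name = ".hh_rk4_cpp")]]
NumericMatrix hh_rk4_cpp(NumericVector stim_time_ms, NumericVector stim_i,
                         double duration_ms, double dt_ms,
                         NumericVector params, double v0,
                         int store_every) {
  HHP p;
  p.Cm = params[0]; p.gK = params[1]; p.gNa = params[2]; p.gL = params[3];
  p.VK = params[4]; p.VNa = params[5]; p.VL = params[6];

  double t0 = stim_time_ms.size() > 0 ? stim_time_ms[0] : 0.0;
  double dt_s = stim_time_ms.size() > 1 ? stim_time_ms[1] - stim_time_ms[0] : 1.0;

  int nstep = (int)std::llround(duration_ms / dt_ms);
  int nout = nstep / store_every + 1;
  NumericMatrix out(nout, 5);

  double s[4], k1[4], k2[4], k3[4], k4[4], tmp[4];
  s[0] = v0;
  s[1] = an_(v0) / (an_(v0) + bn_(v0));
  s[2] = am_(v0) / (am_(v0) + bm_(v0));
  s[3] = ah_(v0) / (ah_(v0) + bh_(v0));

  int row = 0;
  out(row, 0) = 0.0; out(row, 1) = s[0];
  out(row, 2) = s[1]; out(row, 3) = s[2]; out(row, 4) = s[3];
  ++row;

  for (int k = 0; k < nstep; ++k) {
    double t = k * dt_ms;
    double I1 = stim_at(t, stim_i, t0, dt_s);
    double Ih = stim_at(t + 0.5 * dt_ms, stim_i, t0, dt_s);
    double I2 = stim_at(t + dt_ms, stim_i, t0, dt_s);

    hh_rhs(s, I1, p, k1);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt_ms * k1[j];
    hh_rhs(tmp, Ih, p, k2);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + 0.5 * dt_ms * k2[j];
    hh_rhs(tmp, Ih, p, k3);
    for (int j = 0; j < 4; ++j) tmp[j] = s[j] + dt_ms * k3[j];
    hh_rhs(tmp, I2, p, k4);
    for (int j = 0; j < 4; ++j)
      s[j] += dt_ms / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    if (!std::isfinite(s[0]))
      stop("Hodgkin-Huxley state became non-finite at t = %f ms", t + dt_ms);

    if ((k + 1) % store_every == 0 && row < nout) {
      out(row, 0) = (k + 1) * dt_ms;
      out(row, 1) = s[0]; out(row, 2) = s[1];
      out(row, 3) = s[2]; out(row, 4) = s[3];
      ++row;
    }
  }
  return out;
}

// Driven damped single-mode resonator x'' + (w0/Q) x' + w0^2 x = w0^2 f(t),
// integrated by RK4 on the forcing sample grid with linear interpolation at
// half steps.  Initial condition: static equilibrium at the first forcing
// value (x = f[0], x' = 0), which removes the bias-step transient.
// [[Rcpp::export(name = ".resonator_rk4_cpp")]]
NumericVector resonator_rk4_cpp(NumericVector forcing, double dt,
                                double w0, double Q) {
  int n = forcing.size();
  NumericVector out(n);
  double x = forcing[0], v = 0.0;
  double c = w0 / Q, w2 = w0 * w0;
  out[0] = x;
  for (int k = 0; k < n - 1; ++k) {
    double f1 = forcing[k];
    double f2 = forcing[k + 1];
    double fh = 0.5 * (f1 + f2);

    double k1x = v;
    double k1v = w2 * (f1 - x) - c * v;
    double x2 = x + 0.5 * dt * k1x, v2 = v + 0.5 * dt * k1v;
    double k2x = v2, k2v = w2 * (fh - x2) - c * v2;
    double x3 = x + 0.5 * dt * k2x, v3 = v + 0.5 * dt * k2v;
    double k3x = v3, k3v = w2 * (fh - x3) - c * v3;
    double x4 = x + dt * k3x, v4 = v + dt * k3v;
    double k4x = v4, k4v = w2 * (f2 - x4) - c * v4;

    x += dt / 6.0 * (k1x + 2.0 * k2x + 2.0 * k3x + k4x);
    v += dt / 6.0 * (k1v + 2.0 * k2v + 2.0 * k3v + k4v);
    out[k + 1] = x;
  }
  return out;
}

// Sample-wise self-consistent axial magnetization for a field record.
// Same damped fixed point as the R solver, warm-started from the previous
// sample (the map is quasi-static, so the previous solution is an
// excellent initial guess).
// [[Rcpp::export(name = ".axial_chain_cpp")]]
NumericVector axial_chain_cpp(NumericVector H_app, double Ms, double chi0,
                              double N_demag, double gamma, double tol,
                              int max_iter) {
  int n = H_app.size();
  NumericVector M_out(n);
  double M = 0.0;
  double atol = tol * Ms;
  // cap damping so the damped Picard iteration contracts even where the
  // anhysteretic slope is steepest (|slope| <= chi0 * N_demag)
  double g = std::min(gamma, 1.5 / (1.0 + chi0 * N_demag));
  for (int i = 0; i < n; ++i) {
    double Ha = H_app[i];
    bool ok = false;
    for (int it = 0; it < max_iter; ++it) {
      double Heff = Ha - N_demag * M;
      double x = 3.0 * chi0 * std::fabs(Heff) / Ms;
      double L = (x < 1e-4) ? (x / 3.0 - x * x * x / 45.0)
                            : (1.0 / std::tanh(x) - 1.0 / x);
      double target = Ms * L * ((Heff >= 0.0) ? 1.0 : -1.0);
      double M_new = (1.0 - g) * M + g * target;
      double res = std::fabs(M_new - M);
      M = M_new;
      if (res <= atol) { ok = true; break; }
    }
    if (!ok)
      stop("magnetization fixed point failed to converge at sample %d", i + 1);
    M_out[i] = M;
  }
  return M_out;
}
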
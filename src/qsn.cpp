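// Fixed-step integration loops for the silicon neuron models and the
// all-to-all network co-simulation. The R layer owns all parameter
// validation; these routines assume well-formed inputs.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// piecewise-constant stimulus lookup with a moving cursor (segments sorted,
// query times non-decreasing)
struct Stim {
  const double *start, *end, *amp;
  int n, cur;
  Stim(const NumericVector& s, const NumericVector& e, const NumericVector& a)
    : start(s.begin()), end(e.begin()), amp(a.begin()), n(s.size()), cur(0) {}
  double at(double t) {
    while (cur < n && t >= end[cur]) ++cur;
    int i = cur;
    if (i < n && t >= start[i] && t < end[i]) return amp[i];
    return 0.0;
  }
};

static inline double sigm(double M, double delta, double k, double v) {
  return M / (1.0 + std::exp(-k * (v - delta)));
}

// ---------------------------------------------------------------- analog SN
struct AnalogP {
  double C_v, I_a, tau_n, tau_q, M_m, d_m, M_n, d_n, M_q, d_q, S, th_v;
  double k, shal; // kappa/U_T and 1 + 1/kappa
};

static inline void analog_rhs(const AnalogP& p, const double* s, double Istim,
                              double* ds) {
  double v = s[0], n = s[1], q = s[2];
  double g = p.S * std::tanh(0.5 * p.k * (v - p.th_v) / p.shal);
  ds[0] = (-g + sigm(p.M_m, p.d_m, p.k, v) - n - q + p.I_a + Istim) / p.C_v;
  ds[1] = (sigm(p.M_n, p.d_n, p.k, v) - n) / p.tau_n;
  ds[2] = (sigm(p.M_q, p.d_q, p.k, v) - q) / p.tau_q;
}

// [[Rcpp::export]]
NumericMatrix analog_rk4_cpp(NumericVector par, NumericVector s0,
                             NumericVector stim_start, NumericVector stim_end,
                             NumericVector stim_amp, double dt, int n_steps,
                             double v_bound) {
  AnalogP p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
               par[8], par[9], par[10], par[11], par[12], par[13]};
  Stim st(stim_start, stim_end, stim_amp);
  NumericMatrix out(n_steps + 1, 3);
  double s[3] = {s0[0], s0[1], s0[2]};
  double k1[3], k2[3], k3[3], k4[3], tmp[3];
  out(0, 0) = s[0]; out(0, 1) = s[1]; out(0, 2) = s[2];
  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    double I0 = st.at(t), Ih = st.at(t + 0.5 * dt), I1 = st.at(t + dt);
    analog_rhs(p, s, I0, k1);
    for (int j = 0; j < 3; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    analog_rhs(p, tmp, Ih, k2);
    for (int j = 0; j < 3; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    analog_rhs(p, tmp, Ih, k3);
    for (int j = 0; j < 3; ++j) tmp[j] = s[j] + dt * k3[j];
    analog_rhs(p, tmp, I1, k4);
    for (int j = 0; j < 3; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > v_bound)
      stop("numerical blow-up at t = %g s (|v| exceeded %g)", t + dt, v_bound);
    out(i + 1, 0) = s[0]; out(i + 1, 1) = s[1]; out(i + 1, 2) = s[2];
  }
  return out;
}

// ------------------------------------------------------------------- ULP SN
struct UlpP {
  double C_v, C_n, I_av, I_an, I_0P;
  double Mv, dv, Rv20, Rv21, thv;
  double Mn, dn, Rn20, Rn21, thn;
  double th_r, k;
};

static inline double ulp_gx(double I_0P, double R20, double R21, double th,
                            double k, double v) {
  // log-domain: I_0P*R20*exp(k*th) / (1 + R21*exp(-k*(v-th)))
  double la = std::log(R21) - k * (v - th);
  double l1p = la > 33.0 ? la : std::log1p(std::exp(la));
  return std::exp(std::log(I_0P * R20) + k * th - l1p);
}

static inline double ulp_r_of(double I_0P, double th_r, double k, double n) {
  double plateau = I_0P * std::exp(k * th_r);
  return plateau / (1.0 + std::exp(-k * (n - th_r)));
}

static inline void ulp_rhs(const UlpP& p, const double* s, double Istim,
                           bool transformed, double* ds) {
  double v = s[0];
  double fv = sigm(p.Mv, p.dv, p.k, v) -
              ulp_gx(p.I_0P, p.Rv20, p.Rv21, p.thv, p.k, v) + p.I_av;
  double fn = sigm(p.Mn, p.dn, p.k, v) -
              ulp_gx(p.I_0P, p.Rn20, p.Rn21, p.thn, p.k, v) + p.I_an;
  if (!transformed) {
    double rn = ulp_r_of(p.I_0P, p.th_r, p.k, s[1]);
    ds[0] = (fv - rn + Istim) / p.C_v;
    ds[1] = (fn - rn) / p.C_n;
  } else {
    double nt = s[1];
    double plateau = p.I_0P * std::exp(p.k * p.th_r);
    double u = nt / plateau;
    if (u <= 0.0 || u >= 1.0) { ds[0] = ds[1] = NA_REAL; return; }
    // r'(r^{-1}(nt)) = k * nt * (1 - nt/plateau)
    double rp = p.k * nt * (1.0 - u);
    ds[0] = (fv - nt + Istim) / p.C_v;
    ds[1] = rp * (fn - nt) / p.C_n;
  }
}

// [[Rcpp::export]]
NumericMatrix ulp_rk4_cpp(NumericVector par, NumericVector s0,
                          NumericVector stim_start, NumericVector stim_end,
                          NumericVector stim_amp, double dt, int n_steps,
                          double v_bound, bool transformed) {
  UlpP p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
            par[8], par[9], par[10], par[11], par[12], par[13], par[14],
            par[15], par[16]};
  Stim st(stim_start, stim_end, stim_amp);
  NumericMatrix out(n_steps + 1, 2);
  double s[2] = {s0[0], s0[1]};
  double k1[2], k2[2], k3[2], k4[2], tmp[2];
  out(0, 0) = s[0]; out(0, 1) = s[1];
  for (int i = 0; i < n_steps; ++i) {
    double t = i * dt;
    double I0 = st.at(t), Ih = st.at(t + 0.5 * dt), I1 = st.at(t + dt);
    ulp_rhs(p, s, I0, transformed, k1);
    for (int j = 0; j < 2; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    ulp_rhs(p, tmp, Ih, transformed, k2);
    for (int j = 0; j < 2; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    ulp_rhs(p, tmp, Ih, transformed, k3);
    for (int j = 0; j < 2; ++j) tmp[j] = s[j] + dt * k3[j];
    ulp_rhs(p, tmp, I1, transformed, k4);
    for (int j = 0; j < 2; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2 * k2[j] + 2 * k3[j] + k4[j]);
    if (transformed) {
      // keep ntilde strictly inside the open range of r
      double plateau = p.I_0P * std::exp(p.k * p.th_r);
      if (s[1] <= 0.0) s[1] = plateau * 1e-15;
      if (s[1] >= plateau) s[1] = plateau * (1.0 - 1e-15);
    }
    if (!std::isfinite(s[0]) || std::fabs(s[0]) > v_bound)
      stop("numerical blow-up at t = %g s (|v| exceeded %g)", t + dt, v_bound);
    out(i + 1, 0) = s[0]; out(i + 1, 1) = s[1];
  }
  return out;
}

// -------------------------------------------------------------------- DSSN
struct Fx {               // fixed-point context; frac_bits == 0 => double
  int frac_bits; bool nearest; bool err_on_overflow;
  double eps, lo, hi;
  bool active() const { return frac_bits > 0; }
  double q(double x) const {
    if (!active()) return x;
    double s = x / eps;
    double v = nearest ? std::floor(s + 0.5) : std::floor(s);
    v *= eps;
    if (v < lo || v > hi) {
      if (err_on_overflow)
        stop("fixed-point overflow: %g outside [%g, %g]", x, lo, hi);
      v = v < lo ? lo : hi;
    }
    return v;
  }
};

static Fx make_fx(NumericVector fmt) {
  Fx f;
  f.frac_bits = (int)fmt[0];
  f.nearest = fmt[1] > 0.5;
  f.err_on_overflow = fmt[2] > 0.5;
  if (f.frac_bits > 0) {
    int total = (int)fmt[3];
    f.eps = std::ldexp(1.0, -f.frac_bits);
    f.hi = std::ldexp(1.0, total - f.frac_bits - 1) - f.eps;
    f.lo = -std::ldexp(1.0, total - f.frac_bits - 1);
  } else { f.eps = 0; f.lo = 0; f.hi = 0; }
  return f;
}

struct DssnP {
  double phi, tau, I_0;
  double a_fn, b_fn, c_fn, a_fp, b_fp, c_fp;
  double a_gn, b_gn, c_gn, a_gp, b_gp, c_gp, r_g;
};

// quadratic a*(v-b)^2 + c with every multiply/add result quantized
static inline double quad_fx(const Fx& fx, double a, double b, double c,
                             double v) {
  double d = fx.q(v - b);
  double d2 = fx.q(d * d);
  double t = fx.q(a * d2);
  return fx.q(t + c);
}

static inline void dssn_step(const DssnP& p, const Fx& fx, double k1,
                             double k2, double Istim, double& v, double& n) {
  double f = v < 0 ? quad_fx(fx, p.a_fn, p.b_fn, p.c_fn, v)
                   : quad_fx(fx, p.a_fp, p.b_fp, p.c_fp, v);
  double g = v < p.r_g ? quad_fx(fx, p.a_gn, p.b_gn, p.c_gn, v)
                       : quad_fx(fx, p.a_gp, p.b_gp, p.c_gp, v);
  double rhs = fx.q(fx.q(fx.q(f - n) + p.I_0) + Istim);
  double dn  = fx.q(g - n);
  v = fx.q(v + fx.q(k1 * rhs));
  n = fx.q(n + fx.q(k2 * dn));
}

// [[Rcpp::export]]
NumericMatrix dssn_euler_cpp(NumericVector par, NumericVector s0,
                             NumericVector stim_start, NumericVector stim_end,
                             NumericVector stim_amp, double dt, int n_steps,
                             double v_bound, NumericVector fmt,
                             bool const_stim) {
  DssnP p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
             par[8], par[9], par[10], par[11], par[12], par[13], par[14],
             par[15]};
  Fx fx = make_fx(fmt);
  Stim st(stim_start, stim_end, stim_amp);
  double k1 = fx.q(p.phi * dt / p.tau), k2 = fx.q(dt / p.tau);
  double I_0 = fx.q(p.I_0);
  DssnP pq = p; pq.I_0 = I_0;
  NumericMatrix out(n_steps + 1, 2);
  double v = fx.q(s0[0]), n = fx.q(s0[1]);
  out(0, 0) = v; out(0, 1) = n;
  for (int i = 0; i < n_steps; ++i) {
    double Istim = const_stim ? stim_amp[0] : st.at(i * dt);
    dssn_step(pq, fx, k1, k2, fx.q(Istim), v, n);
    if (!std::isfinite(v) || std::fabs(v) > v_bound)
      stop("numerical blow-up at t = %g s (|v| exceeded %g)",
           (i + 1) * dt, v_bound);
    out(i + 1, 0) = v; out(i + 1, 1) = n;
  }
  return out;
}

// ------------------------------------------- all-to-all DSSN network + SS
// Co-simulates N DSSN neurons, one kinetic synapse state per neuron, and
// the weighted accumulator, by forward Euler at a common dt. Stimulus
// schedule: a phase-seed pulse of `pulse_steps` steps with per-neuron
// amplitude `pulse_amp`, then sustained per-neuron `I_ext`. Returns the
// spike trains (upward v-crossings of 0, linearly interpolated).
// [[Rcpp::export]]
List assoc_net_cpp(NumericVector par, NumericMatrix W, double c_scale,
                   double alpha, double beta, NumericVector I_ext,
                   NumericVector pulse_amp, int pulse_steps,
                   double dt, int n_steps,
                   NumericVector v0, NumericVector n0, NumericVector Is0,
                   double v_bound) {
  DssnP p = {par[0], par[1], par[2], par[3], par[4], par[5], par[6], par[7],
             par[8], par[9], par[10], par[11], par[12], par[13], par[14],
             par[15]};
  int N = v0.size();
  double k1 = p.phi * dt / p.tau, k2 = dt / p.tau;
  std::vector<double> v(v0.begin(), v0.end()), n(n0.begin(), n0.end()),
      Is(Is0.begin(), Is0.end()), vprev(N), Iss(N),
      Imin(N, 1e300), Imax(N, -1e300);
  std::vector<std::vector<double>> spikes(N);
  Fx fx; fx.frac_bits = 0; fx.eps = 0; fx.lo = fx.hi = 0;
  fx.nearest = false; fx.err_on_overflow = false;
  const double* w = W.begin(); // column-major: W(j,i) = w[i*N + j]
  for (int s = 0; s < n_steps; ++s) {
    // accumulator: Iss_j = c * sum_i W(j,i) Is_i
    std::fill(Iss.begin(), Iss.end(), 0.0);
    for (int i = 0; i < N; ++i) {
      double Isi = Is[i];
      if (Isi == 0.0) continue;
      const double* col = w + (size_t)i * N;
      for (int j = 0; j < N; ++j) Iss[j] += col[j] * Isi;
    }
    // synapse update from current (presynaptic) v, then neuron update
    for (int j = 0; j < N; ++j) {
      vprev[j] = v[j];
      if (v[j] >= 0.0) Is[j] += dt * alpha * (1.0 - Is[j]);
      else             Is[j] -= dt * beta * Is[j];
      if (Is[j] < 0.0) Is[j] = 0.0;
      if (Is[j] > 1.0) Is[j] = 1.0;
    }
    for (int j = 0; j < N; ++j) {
      // phase-seed window: only the pulsed (+1-pixel) neurons are driven;
      // the sustained stimulus to every neuron starts when it ends
      double Istim = (s < pulse_steps ? pulse_amp[j] : I_ext[j]) +
                     c_scale * Iss[j];
      if (Istim < Imin[j]) Imin[j] = Istim;
      if (Istim > Imax[j]) Imax[j] = Istim;
      dssn_step(p, fx, k1, k2, Istim, v[j], n[j]);
      if (!std::isfinite(v[j]) || std::fabs(v[j]) > v_bound)
        stop("network blow-up at t = %g s, neuron %d", (s + 1) * dt, j + 1);
      if (vprev[j] < 0.0 && v[j] >= 0.0) {
        double frac = -vprev[j] / (v[j] - vprev[j]);
        spikes[j].push_back((s + frac) * dt);
      }
    }
  }
  List trains(N);
  for (int j = 0; j < N; ++j) trains[j] = NumericVector(spikes[j].begin(),
                                                        spikes[j].end());
  return List::create(_["spikes"] = trains,
                      _["v"] = NumericVector(v.begin(), v.end()),
                      _["n"] = NumericVector(n.begin(), n.end()),
                      _["Is"] = NumericVector(Is.begin(), Is.end()),
                      _["I_min"] = NumericVector(Imin.begin(), Imin.end()),
                      _["I_max"] = NumericVector(Imax.begin(), Imax.end()));
}

// -------------------------------------------------- STDP batch weight update
// For every ordered pair (j, i), sum the exponential learning curve over the
// nearest-neighbour pairings: for each spike of postsynaptic j, the signed
// time to the nearest spike of presynaptic i.
// [[Rcpp::export]]
NumericMatrix stdp_dw_cpp(List trains, double A_plus, double A_minus,
                          double tau_plus, double tau_minus) {
  int N = trains.size();
  std::vector<NumericVector> tr(N);
  for (int i = 0; i < N; ++i) tr[i] = trains[i];
  NumericMatrix dW(N, N);
  for (int j = 0; j < N; ++j) {
    const NumericVector& tj = tr[j];
    if (tj.size() == 0) continue;
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      const NumericVector& ti = tr[i];
      int m = ti.size();
      if (m == 0) continue;
      double acc = 0.0;
      int cur = 0;
      for (int a = 0; a < tj.size(); ++a) {
        double t = tj[a];
        while (cur + 1 < m && std::fabs(ti[cur + 1] - t) <=
                              std::fabs(ti[cur] - t)) ++cur;
        double adt = std::fabs(t - ti[cur]);
        acc += A_plus * std::exp(-adt / tau_plus) -
               A_minus * std::exp(-adt / tau_minus);
      }
      dW(j, i) = acc;
    }
  }
  return dW;
}
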
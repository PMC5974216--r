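// Core simulation loops: single-neuron backends and the network engine.
//
// Numerical conventions (mirrored by the R-level step functions, which the
// test suite checks against these loops):
//   per-step order: (1) propagate/decay, (2) add due input, (3) threshold
//   test, (4) record.  Spike times are end-of-step grid times (step k emits
//   at (k+1)*h).  Grid backends count refractoriness in integer steps
//   round(tau_ref/h); the precise backend uses a continuous end time.
//
// s16.15 fixed point: raw int32 value = floor(x * 2^15); multiplication
// forms a 64-bit product then truncates (arithmetic shift) to 15 fractional
// bits; addition saturates at the int32 bounds.

#include <Rcpp.h>
#include <cstdint>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const int64_t FX_ONE = 32768;           // 2^15
const int64_t FX_MAX = INT32_MAX;
const int64_t FX_MIN = INT32_MIN;

inline int64_t fx_from(double x) {
  return (int64_t)std::floor(x * (double)FX_ONE);
}
// constants (propagator entries, thresholds, DC values) are converted with
// round-to-nearest, as a compiler converting literals would; run-time
// arithmetic truncates (fx_mul)
inline int64_t fx_const(double x) {
  return (int64_t)std::llround(x * (double)FX_ONE);
}
inline double fx_val(int64_t r) { return (double)r / (double)FX_ONE; }
inline int64_t fx_mul(int64_t a, int64_t b) {
  return (a * b) >> 15;                 // arithmetic shift: floor
}
inline int64_t fx_sat_add(int64_t a, int64_t b, long long *ovf) {
  int64_t s = a + b;
  if (s > FX_MAX) { if (ovf) ++*ovf; return FX_MAX; }
  if (s < FX_MIN) { if (ovf) ++*ovf; return FX_MIN; }
  return s;
}

struct LifPar {
  double tau_m, tau_s, tau_ref, R_m, E_L, theta, V_r;
};

LifPar read_params(const List &p) {
  LifPar q;
  q.tau_m  = as<double>(p["tau_m"]);
  q.tau_s  = as<double>(p["tau_s"]);
  q.tau_ref= as<double>(p["tau_ref"]);
  q.R_m    = as<double>(p["R_m"]);
  q.E_L    = as<double>(p["E_L"]);
  q.theta  = as<double>(p["theta"]);
  q.V_r    = as<double>(p["V_r"]);
  return q;
}

struct Prop {
  double alpha, beta, P21, q_charge, Rm1ma;
};

Prop make_prop(const LifPar &p, double h) {
  Prop pr;
  pr.alpha = std::exp(-h / p.tau_m);
  pr.beta  = std::exp(-h / p.tau_s);
  if (p.tau_s == p.tau_m) {
    pr.P21 = p.R_m * (h / p.tau_m) * pr.alpha;   // removable singularity
  } else {
    pr.P21 = p.R_m * p.tau_s * (pr.beta - pr.alpha) / (p.tau_s - p.tau_m);
  }
  pr.q_charge = p.tau_s * (1.0 - pr.beta) / h;
  pr.Rm1ma = p.R_m * (1.0 - pr.alpha);
  return pr;
}

// Subthreshold closed form from state (V0, I0) at relative time t, with a
// constant DC current: the analytical solution of the coupled linear system.
inline double v_closed(const LifPar &p, double V0, double I0, double I_dc,
                       double t) {
  double em = std::exp(-t / p.tau_m);
  double P21t;
  if (p.tau_s == p.tau_m) {
    P21t = p.R_m * (t / p.tau_m) * em;
  } else {
    double es = std::exp(-t / p.tau_s);
    P21t = p.R_m * p.tau_s * (es - em) / (p.tau_s - p.tau_m);
  }
  return p.E_L + (V0 - p.E_L) * em + I0 * P21t +
         p.R_m * I_dc * (1.0 - em);
}

// Earliest t* in [0, dt] with V(t*) == theta, or -1 if none.  Scans for a
// sign change on a fine grid (the trajectory has at most one interior
// maximum), then bisects to tolerance tol.
double precise_crossing(const LifPar &p, double V0, double I0, double I_dc,
                        double dt, double tol) {
  if (V0 >= p.theta) return 0.0;
  const int n_scan = 64;
  double lo = 0.0, flo = V0 - p.theta, hi = -1.0;
  for (int i = 1; i <= n_scan; ++i) {
    double t = dt * (double)i / n_scan;
    double f = v_closed(p, V0, I0, I_dc, t) - p.theta;
    if (f >= 0.0) { hi = t; break; }
    lo = t; flo = f;
  }
  if (hi < 0.0) return -1.0;
  while (hi - lo > tol) {
    double mid = 0.5 * (lo + hi);
    double f = v_closed(p, V0, I0, I_dc, mid) - p.theta;
    if (f >= 0.0) hi = mid; else { lo = mid; flo = f; }
  }
  return 0.5 * (lo + hi);
}

} // namespace

// [[Rcpp::export]]
double cpp_precise_crossing(List params, double V0, double I0, double I_dc,
                            double dt, double tol) {
  LifPar p = read_params(params);
  return precise_crossing(p, V0, I0, I_dc, dt, tol);
}

// backend codes: 0 exact-grid, 1 exponential-grid, 2 exponential-fixed,
//                3 precise
// [[Rcpp::export]]
List cpp_run_single_neuron(List params, int backend, IntegerVector counts,
                           double h, double J, int frac_bits,
                           double tol, bool decay_then_add, double I_dc,
                           bool record_trace) {
  LifPar p = read_params(params);
  Prop pr = make_prop(p, h);
  const int n = counts.size();
  const int ref_steps = (int)std::lround(p.tau_ref / h);
  std::vector<double> spikes;
  NumericVector trace(record_trace ? n : 0);

  if (backend == 3) {
    // precise: off-grid threshold crossing on the closed-form solution;
    // inputs delivered at grid times (start of step), continuous
    // refractoriness.
    double V = p.E_L, I = 0.0;
    double ref_until = -1.0;
    for (int k = 0; k < n; ++k) {
      double t0 = k * h;
      I += counts[k] * J;               // grid-constrained delivery
      double cur = 0.0;                 // position within the step
      while (cur < h) {
        if (ref_until > t0 + cur) {
          double rel = std::min(ref_until - t0, (double)h) - cur;
          I *= std::exp(-rel / p.tau_s);
          V = p.V_r;
          cur += rel;
          continue;
        }
        double dt = h - cur;
        double tc = precise_crossing(p, V, I, I_dc, dt, tol);
        if (tc < 0.0) {
          V = v_closed(p, V, I, I_dc, dt);
          I *= std::exp(-dt / p.tau_s);
          cur = h;
        } else {
          double t_sp = t0 + cur + tc;
          spikes.push_back(t_sp);
          I *= std::exp(-tc / p.tau_s);
          V = p.V_r;
          ref_until = t_sp + p.tau_ref;
          cur += tc;
          if (tc == 0.0 && p.tau_ref == 0.0)
            stop("zero refractory period with instantaneous re-crossing");
        }
      }
      if (record_trace) trace[k] = (ref_until > (k + 1) * h) ? p.V_r : V;
    }
  } else if (backend == 2) {
    // s16.15 state; weights quantized to an unsigned (16, frac_bits)
    // format, accumulated with 16-bit saturation, then converted to s16.15
    // by truncation.
    if (frac_bits < 0 || frac_bits > 16) stop("frac_bits must be in 0..16");
    long long ovf = 0;
    const int64_t alpha_r = fx_const(pr.alpha);
    const int64_t beta_r  = fx_const(pr.beta);
    const int64_t q_r     = fx_const(decay_then_add ? pr.beta : pr.q_charge);
    const int64_t rm1ma_r = fx_const(pr.Rm1ma);
    const int64_t EL_r    = fx_const(p.E_L);
    const int64_t th_r    = fx_const(p.theta);
    const int64_t Vr_r    = fx_const(p.V_r);
    const int64_t idc_r   = fx_const(I_dc);
    const int64_t wmax16  = 65535;
    int64_t Jw = (int64_t)std::floor(J * std::pow(2.0, frac_bits));
    if (Jw < 0 || Jw > wmax16) stop("weight not representable in 16 bits");
    int64_t V = EL_r, I = 0;
    int ref = 0;
    for (int k = 0; k < n; ++k) {
      // ring-buffer element for this step: counts[k] saturating adds of Jw
      int64_t acc = 0;
      for (int c = 0; c < counts[k]; ++c) {
        acc += Jw;
        if (acc > wmax16) { acc = wmax16; ++ovf; }
      }
      int64_t del = (frac_bits <= 15) ? (acc << (15 - frac_bits))
                                      : (acc >> (frac_bits - 15));
      I = fx_sat_add(fx_mul(I, beta_r), fx_mul(q_r, del), NULL);
      int64_t Vn = fx_sat_add(
          fx_sat_add(EL_r, fx_mul(V - EL_r, alpha_r), NULL),
          fx_mul(fx_sat_add(I, idc_r, NULL), rm1ma_r), NULL);
      if (ref > 0) {
        Vn = Vr_r;
        --ref;
      } else if (Vn >= th_r) {
        spikes.push_back((k + 1) * h);
        Vn = Vr_r;
        ref = ref_steps;
      }
      V = Vn;
      if (record_trace) trace[k] = fx_val(V);
    }
    List out = List::create(_["spikes"] = wrap(spikes),
                            _["trace"] = trace,
                            _["overflow_count"] = (double)ovf);
    return out;
  } else {
    // float grid backends
    double V = p.E_L, I = 0.0;
    int ref = 0;
    const bool exact = (backend == 0);
    const double q = decay_then_add ? pr.beta : pr.q_charge;
    for (int k = 0; k < n; ++k) {
      double w_in = counts[k] * J;
      double Vn;
      if (exact) {
        Vn = p.E_L + (V - p.E_L) * pr.alpha + I * pr.P21 +
             p.R_m * I_dc * (1.0 - pr.alpha);
        I = pr.beta * I + w_in;
      } else {
        I = pr.beta * I + q * w_in;
        Vn = p.E_L + (V - p.E_L) * pr.alpha + (I + I_dc) * pr.Rm1ma;
      }
      if (ref > 0) {
        Vn = p.V_r;
        --ref;
      } else if (Vn >= p.theta) {
        spikes.push_back((k + 1) * h);
        Vn = p.V_r;
        ref = ref_steps;
      }
      V = Vn;
      if (record_trace) trace[k] = V;
    }
  }
  return List::create(_["spikes"] = wrap(spikes),
                      _["trace"] = trace,
                      _["overflow_count"] = 0.0);
}

// Network engine.
//
// Synapses are passed in CSR layout grouped by source neuron.  Ring buffers
// are per neuron and per synapse type (excitatory/inhibitory accumulate
// separately, signs applied at delivery).  The buffer is circular over
// n_slots >= max delay + 1 elements indexed by delivery step; all additions
// to an element occur while it is not current, and it is zeroed when read,
// which reproduces the accumulate/read/clear semantics of a rotating
// 16-slot buffer chained with delay-extension stages.
//
// backend codes as above (0 exact, 1 exponential, 2 exponential-fixed).
// [[Rcpp::export]]
List cpp_run_network(List params, int backend, double h, int n_steps,
                     IntegerVector syn_ptr, IntegerVector syn_tgt,
                     NumericVector syn_w, IntegerVector syn_d,
                     IntegerVector syn_type, IntegerVector syn_wraw,
                     IntegerVector frac_bits_exc, IntegerVector frac_bits_inh,
                     NumericVector V0, NumericVector I_dc,
                     NumericVector lambda_ext, NumericVector w_ext,
                     IntegerVector w_ext_raw, bool poisson_drive,
                     int n_slots, bool record_state) {
  LifPar p = read_params(params);
  Prop pr = make_prop(p, h);
  const int N = V0.size();
  const int ref_steps = (int)std::lround(p.tau_ref / h);
  const bool fixed = (backend == 2);
  const bool exact = (backend == 0);
  const int64_t wmax16 = 65535;

  std::vector<double> V(N), I(N, 0.0);
  std::vector<int64_t> Vr_(fixed ? N : 0), Ir_(fixed ? N : 0);
  std::vector<int> ref(N, 0);
  std::vector<double> buf;       // float accumulators [neuron][type][slot]
  std::vector<int32_t> bufq;     // fixed accumulators
  if (fixed) bufq.assign((size_t)N * 2 * n_slots, 0);
  else buf.assign((size_t)N * 2 * n_slots, 0.0);

  const int64_t alpha_r = fx_const(pr.alpha);
  const int64_t beta_r  = fx_const(pr.beta);
  const int64_t q_r     = fx_const(pr.q_charge);
  const int64_t rm1ma_r = fx_const(pr.Rm1ma);
  const int64_t EL_r    = fx_const(p.E_L);
  const int64_t th_r    = fx_const(p.theta);
  const int64_t VrR     = fx_const(p.V_r);

  if (fixed) {
    for (int i = 0; i < N; ++i) Vr_[i] = fx_from(V0[i]);  // state: truncate
  } else {
    for (int i = 0; i < N; ++i) V[i] = V0[i];
  }

  long long ovf = 0;        // ring-buffer saturating additions
  long long ovf_state = 0;  // s16.15 state saturations (diagnostic)
  // signed conservation bookkeeping (excitatory positive, inhibitory
  // negative): routed = delivered + remaining-in-buffers + saturated excess
  double total_routed = 0.0, total_delivered = 0.0, sat_excess = 0.0;
  double total_external = 0.0;
  std::vector<int> sp_id;
  std::vector<double> sp_t;
  std::vector<int> fired;
  fired.reserve(1024);

  std::vector<int64_t> idc_r(fixed ? N : 0);
  std::vector<double> scale_e(N), scale_i(N);
  if (fixed) {
    for (int i = 0; i < N; ++i) {
      idc_r[i] = fx_const(I_dc[i]);
      scale_e[i] = std::pow(2.0, -frac_bits_exc[i]);
      scale_i[i] = std::pow(2.0, -frac_bits_inh[i]);
    }
  }

  for (int t = 0; t < n_steps; ++t) {
    const int slot = t % n_slots;
    fired.clear();
    for (int i = 0; i < N; ++i) {
      // (4->1) external drive for this step, then deliver due element
      if (fixed) {
        size_t be = ((size_t)i * 2) * n_slots + slot;
        size_t bi = ((size_t)i * 2 + 1) * n_slots + slot;
        int64_t acc_e = bufq[be], acc_i = bufq[bi];
        if (poisson_drive && lambda_ext[i] > 0) {
          int c = (int)R::rpois(lambda_ext[i]);
          int64_t before = acc_e;
          for (int k = 0; k < c; ++k) {
            acc_e += w_ext_raw[i];
            if (acc_e > wmax16) { acc_e = wmax16; ++ovf; }
          }
          total_external += (acc_e - before) * scale_e[i];
        }
        bufq[be] = 0; bufq[bi] = 0;
        int fe = frac_bits_exc[i], fi = frac_bits_inh[i];
        int64_t de = (fe <= 15) ? (acc_e << (15 - fe)) : (acc_e >> (fe - 15));
        int64_t di = (fi <= 15) ? (acc_i << (15 - fi)) : (acc_i >> (fi - 15));
        total_delivered += fx_val(de) - fx_val(di);
        int64_t din = de - di;
        Ir_[i] = fx_sat_add(fx_mul(Ir_[i], beta_r), fx_mul(q_r, din),
                            &ovf_state);
        int64_t Vn = fx_sat_add(
            fx_sat_add(EL_r, fx_mul(Vr_[i] - EL_r, alpha_r), &ovf_state),
            fx_mul(fx_sat_add(Ir_[i], idc_r[i], &ovf_state), rm1ma_r),
            &ovf_state);
        if (ref[i] > 0) {
          Vn = VrR; --ref[i];
        } else if (Vn >= th_r) {
          fired.push_back(i);
          Vn = VrR; ref[i] = ref_steps;
        }
        Vr_[i] = Vn;
      } else {
        size_t be = ((size_t)i * 2) * n_slots + slot;
        size_t bi = ((size_t)i * 2 + 1) * n_slots + slot;
        double del = buf[be] - buf[bi];
        buf[be] = 0.0; buf[bi] = 0.0;
        if (poisson_drive && lambda_ext[i] > 0) {
          double ext = R::rpois(lambda_ext[i]) * w_ext[i];
          del += ext;
          total_external += ext;
        }
        total_delivered += del;
        double Vn;
        if (exact) {
          Vn = p.E_L + (V[i] - p.E_L) * pr.alpha + I[i] * pr.P21 +
               p.R_m * I_dc[i] * (1.0 - pr.alpha);
          I[i] = pr.beta * I[i] + del;
        } else {
          I[i] = pr.beta * I[i] + pr.q_charge * del;
          Vn = p.E_L + (V[i] - p.E_L) * pr.alpha +
               (I[i] + I_dc[i]) * pr.Rm1ma;
        }
        if (ref[i] > 0) {
          Vn = p.V_r; --ref[i];
        } else if (Vn >= p.theta) {
          fired.push_back(i);
          Vn = p.V_r; ref[i] = ref_steps;
        }
        V[i] = Vn;
      }
    }
    // (3) route emitted spikes into target ring buffers
    const double t_sp = (t + 1) * h;
    for (size_t f = 0; f < fired.size(); ++f) {
      int j = fired[f];
      sp_id.push_back(j + 1);
      sp_t.push_back(t_sp);
      for (int s = syn_ptr[j]; s < syn_ptr[j + 1]; ++s) {
        int tgt = syn_tgt[s];
        int dslot = (t + syn_d[s]) % n_slots;
        int ty = syn_type[s];
        double sgn = (ty == 0) ? 1.0 : -1.0;
        if (fixed) {
          size_t b = ((size_t)tgt * 2 + ty) * n_slots + dslot;
          int64_t v = (int64_t)bufq[b] + syn_wraw[s];
          double scale = (ty == 0) ? scale_e[tgt] : scale_i[tgt];
          if (v > wmax16) {
            ++ovf;
            sat_excess += sgn * (v - wmax16) * scale;
            total_routed += sgn * (wmax16 - bufq[b]) * scale;
            v = wmax16;
          } else {
            total_routed += sgn * syn_wraw[s] * scale;
          }
          bufq[b] = (int32_t)v;
        } else {
          size_t b = ((size_t)tgt * 2 + ty) * n_slots + dslot;
          buf[b] += std::abs(syn_w[s]);
          total_routed += sgn * std::abs(syn_w[s]);
        }
      }
    }
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }

  // weight still sitting in the buffers at the end of the run
  double remaining = 0.0;
  if (fixed) {
    for (int i = 0; i < N; ++i) {
      for (int ty = 0; ty < 2; ++ty) {
        int f_ = (ty == 0) ? frac_bits_exc[i] : frac_bits_inh[i];
        double scale = std::pow(2.0, -f_);
        for (int s = 0; s < n_slots; ++s)
          remaining += bufq[((size_t)i * 2 + ty) * n_slots + s] * scale *
                       (ty == 0 ? 1.0 : -1.0);
      }
    }
  } else {
    for (int i = 0; i < N; ++i)
      for (int s = 0; s < n_slots; ++s)
        remaining += buf[((size_t)i * 2) * n_slots + s] -
                     buf[((size_t)i * 2 + 1) * n_slots + s];
  }

  List out = List::create(
      _["spike_id"] = wrap(sp_id),
      _["spike_time"] = wrap(sp_t),
      _["overflow_count"] = (double)ovf,
      _["state_saturations"] = (double)ovf_state,
      _["total_routed"] = total_routed,
      _["total_delivered"] = total_delivered,
      _["saturated_excess"] = sat_excess,
      _["total_external"] = total_external,
      _["buffer_remaining"] = remaining);
  if (record_state) {
    NumericVector Vout(N);
    for (int i = 0; i < N; ++i) Vout[i] = fixed ? fx_val(Vr_[i]) : V[i];
    out["V_final"] = Vout;
  }
  return out;
}
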
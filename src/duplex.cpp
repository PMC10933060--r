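#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Floating-point simulation loop.
//
// Full stepper: both right-hand sides evaluated every step.
// Duplex stepper: alpha = k_sq*v^2 + 140 - u and beta = a*(b*v - u) are
// recomputed only when the previous step's voltage increment exceeded delta
// in magnitude (strict >); the first step always recomputes (cold cache).
// The reset (v > v_peak -> v = c, u = u + d) is applied after each step; the
// gate compares the pre-reset Euler increment, which at a spike is large, so
// the cache is always refreshed on the step after a reset.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_neuron_cpp(double v0, double u0, double a, double b, double c,
                    double d, double v_peak, NumericVector I, double dt,
                    double delta, bool gated,
                    double k_sq = 0.04, double k_lin = 5.0,
                    double k_off = 140.0) {
  const int n = I.size();
  NumericVector v(n), u(n);
  LogicalVector qs(n), spike(n);
  double vv = v0, uu = u0;
  double alpha = k_sq * vv * vv + k_off - uu;
  double beta  = a * (b * vv - uu);
  double last_dv = R_PosInf;  // cold cache: first step recomputes
  int recompute_count = 0;
  for (int i = 0; i < n; i++) {
    // delta = 0 disables gating entirely (in fixed point an increment can be
    // exactly zero, so a strict ">" gate at 0 would not equal the full path)
    bool rec = !gated || delta <= 0.0 || std::fabs(last_dv) > delta;
    if (rec) {
      alpha = k_sq * vv * vv + k_off - uu;
      beta  = a * (b * vv - uu);
      recompute_count++;
    }
    qs[i] = !rec;
    double vn = (alpha + k_lin * vv + I[i]) * dt + vv;
    double un = beta * dt + uu;
    if (!std::isfinite(vn) || !std::isfinite(un))
      stop("non-finite state at step %d (v=%g, u=%g); aborting", i + 1, vn, un);
    last_dv = vn - vv;
    bool s = vn > v_peak;
    if (s) { vn = c; un += d; }
    spike[i] = s;
    vv = vn; uu = un;
    v[i] = vv; u[i] = uu;
  }
  return List::create(_["v"] = v, _["u"] = u, _["qs"] = qs,
                      _["spike"] = spike,
                      _["recompute_count"] = recompute_count,
                      _["step_count"] = n);
}

// ---------------------------------------------------------------------------
// Fixed-point engine. Raw two's-complement payloads are carried in doubles
// (exact for |raw| < 2^53; word lengths here are <= 40 bits). Quantization is
// round-to-nearest, half away from zero rounding up (hardware adder + floor),
// overflow saturates to the representable range or raises in strict mode.
// ---------------------------------------------------------------------------

static double fx_clamp(double raw, int word_bits, bool strict, bool *flagged) {
  double lim = std::ldexp(1.0, word_bits - 1);
  if (raw >= lim) {
    if (strict) stop("fixed-point overflow: raw %g exceeds %d-bit word", raw, word_bits);
    *flagged = true; return lim - 1.0;
  }
  if (raw < -lim) {
    if (strict) stop("fixed-point overflow: raw %g exceeds %d-bit word", raw, word_bits);
    *flagged = true; return -lim;
  }
  return raw;
}

static double fx_round_half_up(double x) { return std::floor(x + 0.5); }

// [[Rcpp::export]]
List fx_quantize_cpp(NumericVector x, int word_bits, int frac_bits, bool strict) {
  const int n = x.size();
  NumericVector raw(n);
  bool flagged = false;
  double scale = std::ldexp(1.0, frac_bits);
  for (int i = 0; i < n; i++) {
    if (!std::isfinite(x[i])) stop("cannot quantize non-finite value");
    raw[i] = fx_clamp(fx_round_half_up(x[i] * scale), word_bits, strict, &flagged);
  }
  return List::create(_["raw"] = raw, _["overflow"] = flagged);
}

// arithmetic shift of a raw payload: s >= 0 right (floor division, sign
// preserving), s < 0 left.
static double fx_arshift(double raw, int s) {
  if (s >= 0) return std::floor(raw * std::ldexp(1.0, -s));
  return raw * std::ldexp(1.0, -s);
}

// [[Rcpp::export]]
List fx_shiftadd_cpp(NumericVector raw, IntegerVector shifts, int word_bits,
                     bool strict) {
  const int n = raw.size();
  NumericVector out(n);
  bool flagged = false;
  for (int i = 0; i < n; i++) {
    double acc = 0.0;
    for (int j = 0; j < shifts.size(); j++) acc += fx_arshift(raw[i], shifts[j]);
    out[i] = fx_clamp(acc, word_bits, strict, &flagged);
  }
  return List::create(_["raw"] = out, _["overflow"] = flagged);
}

// Linear-mode CORDIC squaring of a fixed-point value. The input value is
// pre-scaled by 2^-e into [-1, 1]; z-driven micro-rotations
//   z_{i+1} = z_i - d_i 2^-i,  y_{i+1} = y_i + d_i m 2^-i,  d_i = sign(z_i)
// accumulate y -> m^2; the scaling is re-applied squared (result * 4^e).
// Two extra iterations per scaling octave keep the absolute error within
// |x| * 2^-n_iter. The recurrence runs on exact dyadic doubles; only the
// final result is quantized back to the format.
static double cordic_square_raw(double raw, int word_bits, int frac_bits,
                                int n_iter, bool strict, bool *flagged,
                                int *iters_used) {
  if (raw == 0.0) { *iters_used = 0; return 0.0; }
  double val = raw * std::ldexp(1.0, -frac_bits);
  int e = 0;
  double av = std::fabs(val);
  while (av > 1.0) { av *= 0.5; e++; }
  double m = std::ldexp(val, -e);
  double z = m, y = 0.0;
  int iters = n_iter + 2 * e;
  for (int i = 1; i <= iters; i++) {
    double p = std::ldexp(1.0, -i);
    if (z >= 0) { z -= p; y += std::ldexp(m, -i); }
    else        { z += p; y -= std::ldexp(m, -i); }
  }
  *iters_used = iters;
  double res = std::ldexp(y, 2 * e);
  return fx_clamp(fx_round_half_up(res * std::ldexp(1.0, frac_bits)),
                  word_bits, strict, flagged);
}

// [[Rcpp::export]]
List fx_cordic_square_cpp(NumericVector raw, int word_bits, int frac_bits,
                          int n_iter, bool strict) {
  const int n = raw.size();
  NumericVector out(n);
  IntegerVector iters(n);
  bool flagged = false;
  for (int i = 0; i < n; i++) {
    int it = 0;
    out[i] = cordic_square_raw(raw[i], word_bits, frac_bits, n_iter, strict,
                               &flagged, &it);
    iters[i] = it;
  }
  return List::create(_["raw"] = out, _["iters"] = iters,
                      _["overflow"] = flagged);
}

// ---------------------------------------------------------------------------
// Fixed-point duplex data path, one neuron, whole run. Mirrors the hardware
// graph: a comparator on |last_dv| vs delta selects QS (alpha/beta registers
// reused) or FS (CORDIC square + register update); all constant multiplies
// are shift-add decompositions; dt is a single arithmetic right shift.
// Operation counters are aggregated per mode.
// ---------------------------------------------------------------------------

struct OpCounters { double adds, shifts, cordic, cmp; };

static int count_real_shifts(IntegerVector sh) {
  int k = 0;
  for (int j = 0; j < sh.size(); j++) if (sh[j] != 0) k++;
  return k;
}

static double shiftadd_acc(double raw, IntegerVector sh) {
  double acc = 0.0;
  for (int j = 0; j < sh.size(); j++) acc += fx_arshift(raw, sh[j]);
  return acc;
}

// [[Rcpp::export]]
List sim_neuron_fx_cpp(double v0_raw, double u0_raw, double c_raw,
                       double d_raw, double v_peak_raw, NumericVector I_raw,
                       double k_off_raw, double delta_raw,
                       IntegerVector sh_sq, IntegerVector sh_b,
                       IntegerVector sh_a, IntegerVector sh_lin,
                       int dt_shift, int word_bits, int frac_bits,
                       int n_iter, bool strict, bool gated) {
  const int n = I_raw.size();
  NumericVector v(n), u(n);
  LogicalVector qs(n), spike(n);
  bool flagged = false;
  double vv = v0_raw, uu = u0_raw;
  double alpha = 0.0, beta = 0.0;
  double last_dv = R_PosInf;
  int recompute_count = 0;
  OpCounters cost[2] = {{0, 0, 0, 0}, {0, 0, 0, 0}};  // 0 = QS, 1 = FS
  const int nsh_sq = count_real_shifts(sh_sq), nsh_b = count_real_shifts(sh_b);
  const int nsh_a = count_real_shifts(sh_a), nsh_lin = count_real_shifts(sh_lin);
  for (int i = 0; i < n; i++) {
    bool rec = !gated || delta_raw <= 0.0 || std::fabs(last_dv) > delta_raw;
    OpCounters &oc = cost[rec ? 1 : 0];
    oc.cmp += 1;  // QS/FS comparator + multiplexer select
    if (rec) {
      int it = 0;
      double sq = cordic_square_raw(vv, word_bits, frac_bits, n_iter, strict,
                                    &flagged, &it);
      oc.cordic += it;
      double t_sq = fx_clamp(shiftadd_acc(sq, sh_sq), word_bits, strict, &flagged);
      oc.shifts += nsh_sq; oc.adds += sh_sq.size() - 1;
      alpha = fx_clamp(t_sq + k_off_raw - uu, word_bits, strict, &flagged);
      oc.adds += 2;
      double bv = fx_clamp(shiftadd_acc(vv, sh_b), word_bits, strict, &flagged);
      oc.shifts += nsh_b; oc.adds += sh_b.size() - 1;
      double t_b = fx_clamp(bv - uu, word_bits, strict, &flagged);
      oc.adds += 1;
      beta = fx_clamp(shiftadd_acc(t_b, sh_a), word_bits, strict, &flagged);
      oc.shifts += nsh_a; oc.adds += sh_a.size() - 1;
      recompute_count++;
    }
    qs[i] = !rec;
    double lin_v = fx_clamp(shiftadd_acc(vv, sh_lin), word_bits, strict, &flagged);
    oc.shifts += nsh_lin; oc.adds += sh_lin.size() - 1;
    double s_sum = fx_clamp(alpha + lin_v + I_raw[i], word_bits, strict, &flagged);
    oc.adds += 2;
    double vn = fx_clamp(fx_arshift(s_sum, dt_shift) + vv, word_bits, strict, &flagged);
    oc.shifts += 1; oc.adds += 1;
    double un = fx_clamp(fx_arshift(beta, dt_shift) + uu, word_bits, strict, &flagged);
    oc.shifts += 1; oc.adds += 1;
    last_dv = vn - vv;
    oc.adds += 1;
    oc.cmp += 1;  // reset comparator
    bool sp = vn > v_peak_raw;
    if (sp) {
      vn = c_raw;
      un = fx_clamp(un + d_raw, word_bits, strict, &flagged);
      oc.adds += 1;
    }
    spike[i] = sp;
    vv = vn; uu = un;
    v[i] = vv; u[i] = uu;
  }
  NumericMatrix costs(2, 4);
  for (int m = 0; m < 2; m++) {
    costs(m, 0) = cost[m].adds;  costs(m, 1) = cost[m].shifts;
    costs(m, 2) = cost[m].cordic; costs(m, 3) = cost[m].cmp;
  }
  return List::create(_["v_raw"] = v, _["u_raw"] = u, _["qs"] = qs,
                      _["spike"] = spike,
                      _["recompute_count"] = recompute_count,
                      _["step_count"] = n, _["costs"] = costs,
                      _["overflow"] = flagged);
}

// ---------------------------------------------------------------------------
// Three-layer feed-forward network (sizes taken from the weight arrays) of
// identical regular-spiking neurons, synchronous stepping, delta-current
// synapses (a presynaptic spike adds the weight to the postsynaptic input for
// the next step), optional duplex gating per neuron, and optional online
// pair-based STDP (exponential pre/post traces = all-to-all pairing).
// During training a teacher current is injected into hidden and output
// neurons while a pattern is on.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List sim_layered_cpp(NumericMatrix W12, NumericVector W23,
                     NumericMatrix patterns,  // P x n1, entries 0/1
                     double a, double b, double c, double d, double v_peak,
                     double dt, double on_ms, double gap_ms,
                     double i_on, double i_off, double i_teach,
                     bool train, double ap, double am, double tau_plus,
                     double tau_minus,
                     double wmin12, double wmax12, double wmin23, double wmax23,
                     double delta, bool gated) {
  const int n1 = W12.nrow(), n2 = W12.ncol(), P = patterns.nrow();
  if (W23.size() != n2) stop("W23 length must match hidden layer size");
  const int on_steps = (int)std::lround(on_ms / dt);
  const int gap_steps = (int)std::lround(gap_ms / dt);
  NumericMatrix W12c = clone(W12);
  NumericVector W23c = clone(W23);
  const int N = n1 + n2 + 1;
  std::vector<double> v(N, -70.0), u(N), alpha(N), beta(N), last_dv(N, R_PosInf);
  std::vector<int> rec(N, 0);
  for (int j = 0; j < N; j++) {
    u[j] = b * v[j];
    alpha[j] = 0.04 * v[j] * v[j] + 140.0 - u[j];
    beta[j] = a * (b * v[j] - u[j]);
  }
  std::vector<int> s1(n1, 0), s2(n2, 0);
  int s3 = 0;
  std::vector<double> xp1(n1, 0.0), xp2(n2, 0.0), xq2(n2, 0.0);
  double xq3 = 0.0;
  const double dec_p = std::exp(-dt / tau_plus), dec_m = std::exp(-dt / tau_minus);
  const double rng12 = wmax12 - wmin12, rng23 = wmax23 - wmin23;
  IntegerVector out_counts(P);
  IntegerMatrix hid_counts(P, n2);
  NumericVector out_v((on_steps + gap_steps) * P);
  int step_total = 0;
  for (int p = 0; p < P; p++) {
    for (int k = 0; k < on_steps + gap_steps; k++) {
      bool on = k < on_steps;
      double teach = (train && on) ? i_teach : 0.0;
      // synaptic input from last step's spikes
      std::vector<double> I(N, 0.0);
      for (int j = 0; j < n1; j++)
        I[j] = on ? (patterns(p, j) > 0 ? i_on : i_off) : 0.0;
      for (int h = 0; h < n2; h++) {
        double acc = teach;
        for (int j = 0; j < n1; j++) if (s1[j]) acc += W12c(j, h);
        I[n1 + h] = acc;
      }
      {
        double acc = teach;
        for (int h = 0; h < n2; h++) if (s2[h]) acc += W23c[h];
        I[N - 1] = acc;
      }
      // advance all neurons one (optionally gated) Euler step
      std::vector<int> f(N, 0);
      for (int j = 0; j < N; j++) {
        bool rc = !gated || delta <= 0.0 || std::fabs(last_dv[j]) > delta;
        if (rc) {
          alpha[j] = 0.04 * v[j] * v[j] + 140.0 - u[j];
          beta[j] = a * (b * v[j] - u[j]);
          rec[j]++;
        }
        double vn = (alpha[j] + 5.0 * v[j] + I[j]) * dt + v[j];
        double un = beta[j] * dt + u[j];
        if (!std::isfinite(vn)) stop("non-finite state in layered net, neuron %d", j + 1);
        last_dv[j] = vn - v[j];
        if (vn > v_peak) { vn = c; un += d; f[j] = 1; }
        v[j] = vn; u[j] = un;
      }
      if (train) {
        for (int j = 0; j < n1; j++) xp1[j] *= dec_p;
        for (int h = 0; h < n2; h++) { xp2[h] *= dec_p; xq2[h] *= dec_m; }
        xq3 *= dec_m;
        // presynaptic spike after postsynaptic trace -> depression
        for (int j = 0; j < n1; j++) if (f[j])
          for (int h = 0; h < n2; h++) W12c(j, h) -= am * rng12 * xq2[h];
        for (int h = 0; h < n2; h++) if (f[n1 + h]) {
          for (int j = 0; j < n1; j++) W12c(j, h) += ap * rng12 * xp1[j];
          W23c[h] -= am * rng23 * xq3;
        }
        if (f[N - 1])
          for (int h = 0; h < n2; h++) W23c[h] += ap * rng23 * xp2[h];
        for (int j = 0; j < n1; j++) if (f[j]) xp1[j] += 1.0;
        for (int h = 0; h < n2; h++) if (f[n1 + h]) { xp2[h] += 1.0; xq2[h] += 1.0; }
        if (f[N - 1]) xq3 += 1.0;
        for (int h = 0; h < n2; h++) {
          for (int j = 0; j < n1; j++) {
            if (W12c(j, h) < wmin12) W12c(j, h) = wmin12;
            if (W12c(j, h) > wmax12) W12c(j, h) = wmax12;
          }
          if (W23c[h] < wmin23) W23c[h] = wmin23;
          if (W23c[h] > wmax23) W23c[h] = wmax23;
        }
      }
      for (int j = 0; j < n1; j++) s1[j] = f[j];
      for (int h = 0; h < n2; h++) {
        s2[h] = f[n1 + h];
        hid_counts(p, h) += f[n1 + h];
      }
      s3 = f[N - 1];
      out_counts[p] += s3;
      out_v[step_total] = v[N - 1];
      step_total++;
    }
  }
  IntegerVector recompute(N), steps(N);
  for (int j = 0; j < N; j++) { recompute[j] = rec[j]; steps[j] = step_total; }
  return List::create(_["W12"] = W12c, _["W23"] = W23c,
                      _["out_counts"] = out_counts,
                      _["hid_counts"] = hid_counts,
                      _["recompute_count"] = recompute,
                      _["step_count"] = steps,
                      _["out_v"] = out_v);
}
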
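#include <Rcpp.h>
using namespace Rcpp;

// Semi-implicit (symplectic) Euler integration of the resonate-and-fire
// neuron with time step dt:
//   x <- x + dt * (b*x - w*y + gs*s(t))
//   y <- y + dt * (w*x_new + b*y)
// Updating y with the already-updated x keeps the discrete rotation
// neutrally stable; the explicit update inflates the oscillation amplitude
// by ~(w*dt)^2/2 per step, which at w*dt ~ 0.07 swamps the weak fitted
// damping within tens of milliseconds and destroys resonance selectivity.
// On an upward crossing of y >= y_thresh a spike is recorded and the state
// reset to (x_reset, y_reset). Because y_reset equals the threshold, a spike
// does not retrigger immediately: the detector re-arms only after y falls
// below threshold again (crossing semantics).
// Units: dt in ms, omega in rad/ms, b in 1/ms.
// [[Rcpp::export(name = ".rf_core")]]
List rf_core(NumericVector s, double dt, double omega, double b, double gs,
             double x_reset, double y_reset, double y_thresh,
             bool keep_traces) {
  int n = s.size();
  NumericVector x_out, y_out;
  if (keep_traces) {
    x_out = NumericVector(n);
    y_out = NumericVector(n);
  }
  std::vector<int> spikes;
  double x = 0.0, y = 0.0;
  bool armed = true;
  for (int i = 0; i < n; ++i) {
    x += (b * x - omega * y + gs * s[i]) * dt;
    y += (omega * x + b * y) * dt;
    if (armed && y >= y_thresh) {
      spikes.push_back(i + 1);  // 1-based sample index
      x = x_reset;
      y = y_reset;
      armed = false;
    } else if (!armed && y < y_thresh) {
      armed = true;
    }
    if (keep_traces) {
      x_out[i] = x;
      y_out[i] = y;
    }
  }
  List out = List::create(_["spikes"] = wrap(spikes));
  if (keep_traces) {
    out["x"] = x_out;
    out["y"] = y_out;
  }
  return out;
}

// Euler integration of the leaky integrate-and-fire neuron with an
// adaptation current (LIFAC):
//   tau_m   dV/dt = -V + I - A
//   tau_ada dA/dt = -A
// On V >= v_thres: spike, V <- v_reset, A <- A + alpha; V and A are then
// frozen for the refractory period tau_ref.
// Units: dt and time constants in ms.
// [[Rcpp::export(name = ".lifac_core")]]
List lifac_core(NumericVector I, double dt, double tau_m, double tau_ada,
                double alpha, double v_thres, double v_reset, double tau_ref,
                bool keep_traces) {
  int n = I.size();
  NumericVector v_out, a_out;
  if (keep_traces) {
    v_out = NumericVector(n);
    a_out = NumericVector(n);
  }
  std::vector<int> spikes;
  double V = 0.0, A = 0.0;
  int refrac = 0;
  int n_ref = (int)std::lround(tau_ref / dt);
  for (int i = 0; i < n; ++i) {
    if (refrac > 0) {
      refrac--;
    } else {
      V += dt * (-V + I[i] - A) / tau_m;
      A += dt * (-A) / tau_ada;
      if (V >= v_thres) {
        spikes.push_back(i + 1);
        V = v_reset;
        A += alpha;
        refrac = n_ref;
      }
    }
    if (keep_traces) {
      v_out[i] = V;
      a_out[i] = A;
    }
  }
  List out = List::create(_["spikes"] = wrap(spikes));
  if (keep_traces) {
    out["V"] = v_out;
    out["A"] = a_out;
  }
  return out;
}

// First-order low-pass: da/dt = (x - a) / tau, a(0) = 0. dt, tau in ms.
// [[Rcpp::export(name = ".lowpass_core")]]
NumericVector lowpass_core(NumericVector x, double dt, double tau) {
  int n = x.size();
  NumericVector a(n);
  double state = 0.0;
  double k = dt / tau;
  for (int i = 0; i < n; ++i) {
    state += k * (x[i] - state);
    a[i] = state;
  }
  return a;
}

// Grid-wide phonotaxis scores for the delay-line models. S holds one
// rendered stimulus per column; scores are means over the window rows
// [wlo, whi] (1-based, inclusive).

// fractional-sample delayed lookup with zero padding: linear interpolation
// between the two straddling integer shifts
static inline double delayed_at(const NumericMatrix& S, int t, int d0,
                                double f, int j) {
  int a = t - d0, b = t - d0 - 1;
  double va = (a >= 0) ? S(a, j) : 0.0;
  if (f < 1e-9) return va;
  double vb = (b >= 0) ? S(b, j) : 0.0;
  return (1.0 - f) * va + f * vb;
}

// autocorrelation: gain * mean(s(t) * s(t - d)), d in (fractional) samples
// [[Rcpp::export(name = ".autocorr_scores_core")]]
NumericVector autocorr_scores_core(NumericMatrix S, double gain, double d,
                                   int wlo, int whi) {
  int m = S.ncol();
  NumericVector out(m);
  double wn = whi - wlo + 1;
  int d0 = (int)std::floor(d);
  double f = d - d0;
  for (int j = 0; j < m; ++j) {
    double acc = 0.0;
    for (int t = wlo - 1; t <= whi - 1; ++t)
      acc += S(t, j) * delayed_at(S, t, d0, f, j);
    out[j] = gain * acc / wn;
  }
  return out;
}

// rebound model (optionally with the feedforward-inhibition path):
// sF(t) = dt * (-ge * box(s, t, ne) + gi * box(s, t - ne, ni)) (the
// reversed-time bi-phasic filter), sR = max(sF, 0), coincidence with the
// stimulus delayed by d samples; with ffi, the same filter form (gfi, gfe,
// nfi, nfe) applied to the stimulus delayed by df samples contributes its
// negative part, and the sum is rectified.
// [[Rcpp::export(name = ".rebound_scores_core")]]
NumericVector rebound_scores_core(NumericMatrix S, double dt, double gi,
                                  int ni, double ge, int ne, double d,
                                  int wlo, int whi, bool ffi, double gfi,
                                  int nfi, double gfe, int nfe, double df) {
  int n = S.nrow(), m = S.ncol();
  NumericVector out(m);
  std::vector<double> C(n + 1);
  double wn = whi - wlo + 1;
  int d0 = (int)std::floor(d);
  double fd = d - d0;
  int df0 = (int)std::floor(df);
  double fdf = df - df0;
  for (int j = 0; j < m; ++j) {
    C[0] = 0.0;
    for (int t = 0; t < n; ++t) C[t + 1] = C[t] + S(t, j);
    double acc = 0.0;
    for (int t = wlo - 1; t <= whi - 1; ++t) {
      int hi1 = t + 1, lo1 = std::max(t + 1 - ne, 0);
      int hi2 = std::max(t + 1 - ne, 0), lo2 = std::max(t + 1 - ne - ni, 0);
      double sF = dt * (-ge * (C[hi1] - C[lo1]) + gi * (C[hi2] - C[lo2]));
      double sR = sF > 0 ? sF : 0.0;
      double val = sR * delayed_at(S, t, d0, fd, j);
      if (ffi) {
        // the feedforward filter runs on the stimulus delayed by df;
        // a fractional df interpolates the two integer-shifted filters
        double w;
        {
          int u = t - df0;
          double w0 = 0.0, w1 = 0.0;
          if (u >= 0) {
            int h1 = u + 1, l1 = std::max(u + 1 - nfe, 0);
            int h2 = std::max(u + 1 - nfe, 0),
                l2 = std::max(u + 1 - nfe - nfi, 0);
            w0 = dt * (-gfe * (C[h1] - C[l1]) + gfi * (C[h2] - C[l2]));
          }
          if (fdf >= 1e-9 && u - 1 >= 0) {
            int h1 = u, l1 = std::max(u - nfe, 0);
            int h2 = std::max(u - nfe, 0), l2 = std::max(u - nfe - nfi, 0);
            w1 = dt * (-gfe * (C[h1] - C[l1]) + gfi * (C[h2] - C[l2]));
          }
          w = (fdf < 1e-9) ? w0 : (1.0 - fdf) * w0 + fdf * w1;
        }
        double inh = w < 0 ? w : 0.0;
        val = val + inh;
        if (val < 0) val = 0.0;
      }
      acc += val;
    }
    out[j] = acc / wn;
  }
  return out;
}
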
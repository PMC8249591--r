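#include <Rcpp.h>
using namespace Rcpp;

// Classical four-state Hodgkin-Huxley squid-axon model.
// Units: V in mV, t in ms, current density in uA/cm^2, conductances mS/cm^2.
// Gates use exponential-Euler updates (unconditionally stable for first-order
// relaxation); the voltage uses forward Euler, stable at the default
// dt = 0.01 ms.

static inline double alpha_m(double V) {
  double x = V + 40.0;
  if (std::fabs(x) < 1e-7) return 1.0;          // limit of x/10/(1-exp(-x/10))
  return 0.1 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_m(double V)  { return 4.0 * std::exp(-(V + 65.0) / 18.0); }
static inline double alpha_h(double V) { return 0.07 * std::exp(-(V + 65.0) / 20.0); }
static inline double beta_h(double V)  { return 1.0 / (1.0 + std::exp(-(V + 35.0) / 10.0)); }
static inline double alpha_n(double V) {
  double x = V + 55.0;
  if (std::fabs(x) < 1e-7) return 0.1;
  return 0.01 * x / (1.0 - std::exp(-x / 10.0));
}
static inline double beta_n(double V)  { return 0.125 * std::exp(-(V + 65.0) / 80.0); }

// [[Rcpp::export]]
NumericMatrix hh_core(NumericVector I, double dt_ms,
                      double gNa, double gK, double gL,
                      double ENa, double EK, double EL,
                      double Cm, double V0) {
  int n = I.size();
  NumericMatrix out(n, 4);   // V, m, h, n
  double V = V0;
  double m = alpha_m(V) / (alpha_m(V) + beta_m(V));
  double h = alpha_h(V) / (alpha_h(V) + beta_h(V));
  double nn = alpha_n(V) / (alpha_n(V) + beta_n(V));
  for (int i = 0; i < n; ++i) {
    double INa = gNa * m * m * m * h * (V - ENa);
    double IK  = gK * nn * nn * nn * nn * (V - EK);
    double IL  = gL * (V - EL);
    double dV  = (I[i] - INa - IK - IL) / Cm;
    V += dt_ms * dV;
    if (!std::isfinite(V))
      stop("Hodgkin-Huxley integration diverged (non-finite V at step %d)", i + 1);
    // exponential Euler on the gates at the updated voltage
    double am = alpha_m(V), bm = beta_m(V);
    double ah = alpha_h(V), bh = beta_h(V);
    double an = alpha_n(V), bn = beta_n(V);
    double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh), tn = 1.0 / (an + bn);
    m  = am * tm + (m  - am * tm) * std::exp(-dt_ms / tm);
    h  = ah * th + (h  - ah * th) * std::exp(-dt_ms / th);
    nn = an * tn + (nn - an * tn) * std::exp(-dt_ms / tn);
    out(i, 0) = V; out(i, 1) = m; out(i, 2) = h; out(i, 3) = nn;
  }
  return out;
}

// Three-store diffusion synapse: free transmitter pool q, synaptic cleft c,
// reprocessing store w.  Release is driven by a saturating (Boltzmann)
// function of the receptor potential.  Forward-Euler updates are applied
// flux-by-flux so that the store budget residual is exactly the integral of
// (manufacture - loss), i.e. total content is conserved up to the explicit
// replenishment and loss fluxes.
//   dq/dt = y (M - q) + x w - k(V) q
//   dc/dt = k(V) q - (l + r) c
//   dw/dt = r c - x w
//   rate  = h c
// [[Rcpp::export]]
List synapse_core(NumericVector vihc, double dt,
                  double y, double M, double xw, double l, double r,
                  double kmax, double vhalf, double sv, double hgain,
                  double q0, double c0, double w0,
                  bool keep_states) {
  int n = vihc.size();
  NumericVector rate(n);
  NumericMatrix st;
  if (keep_states) st = NumericMatrix(n, 3);
  double q = q0, c = c0, w = w0;
  double budget = 0.0;   // running integral of (manufacture - loss) * dt
  double total0 = q + c + w;
  for (int i = 0; i < n; ++i) {
    double k = kmax / (1.0 + std::exp(-(vihc[i] - vhalf) / sv));
    double f_rep = y * (M - q);     // manufacture / replenishment
    double f_rel = k * q;           // release into cleft
    double f_loss = l * c;          // cleft loss
    double f_reup = r * c;          // reuptake to reprocessing
    double f_ret = xw * w;          // return to free pool
    q += dt * (f_rep + f_ret - f_rel);
    c += dt * (f_rel - f_loss - f_reup);
    w += dt * (f_reup - f_ret);
    budget += dt * (f_rep - f_loss);
    if (q < 0 || c < 0 || w < 0)
      stop("synapse integration step failure: negative store content at step %d", i + 1);
    rate[i] = hgain * c;
    if (keep_states) { st(i, 0) = q; st(i, 1) = c; st(i, 2) = w; }
  }
  double residual = (q + c + w) - total0 - budget;
  List out = List::create(_["rate"] = rate,
                          _["final"] = NumericVector::create(q, c, w),
                          _["budget_residual"] = residual);
  if (keep_states) out["states"] = st;
  return out;
}
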
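#include <Rcpp.h>
using namespace Rcpp;

// Exponent guard: keeps alpha/beta finite at extreme voltages.
static inline double clampexp(double x) {
  if (x > 50.0) x = 50.0;
  if (x < -50.0) x = -50.0;
  return std::exp(x);
}

// Backward-Euler cable integrator for a passive + I_h neuron.
//
// Compartment 0 is the soma (injection and recording site); compartments
// 1..n-1, if present, form an unbranched dendrite. Voltage is advanced
// implicitly (tridiagonal solve), the activation gate exponentially against
// its voltage-dependent steady state and time constant evaluated at the
// start of the step.
//
// Units: area cm^2, gbar S/cm^2, g_axial S, Rm ohm*cm^2, Cm uF/cm^2,
// voltages mV, currents pA, times ms.
// [[Rcpp::export]]
NumericVector sim_cable(NumericVector area,
                        NumericVector gbar,
                        NumericVector g_axial,
                        double Rm, double Cm, double e_pas, double Eh,
                        double Vl_half, double kl,
                        double Vt_half, double a0t, double zetat, double gmt,
                        double qt, double cc,
                        double v0, double i_hold_pA, double amp_pA,
                        double onset, double duration, double total, double dt)
{
  const int n = area.size();
  const int nt = (int)std::lround(total / dt) + 1;
  NumericVector vout(nt);
  std::vector<double> V(n, v0), l(n);
  std::vector<double> a(n), b(n), c(n), d(n), cp(n), dp(n);
  for (int i = 0; i < n; ++i)
    l[i] = 1.0 / (1.0 + clampexp(-(v0 - Vl_half) / kl));
  const double gl = 1.0 / Rm; // S/cm^2
  for (int it = 0; it < nt; ++it) {
    vout[it] = V[0];
    if (!R_finite(V[0]) || std::fabs(V[0]) > 200.0) {
      // numerical blow-up: return what we have, caller raises the error
      for (int j = it + 1; j < nt; ++j) vout[j] = NA_REAL;
      return vout;
    }
    double t = it * dt;
    double Iinj = i_hold_pA + ((t >= onset && t < onset + duration) ? amp_pA : 0.0);
    for (int i = 0; i < n; ++i) {
      double li = 1.0 / (1.0 + clampexp(-(V[i] - Vl_half) / kl));
      double al = clampexp(cc * zetat * (V[i] - Vt_half));
      double be = clampexp(cc * zetat * gmt * (V[i] - Vt_half));
      double tl = be / (qt * a0t * (1.0 + al));
      l[i] = li + (l[i] - li) * std::exp(-dt / tl);
    }
    // Row i (all terms in nA, coefficients in uS):
    //   (Cm*area*1e3/dt + g_mem + g_ax) V_i' - sum_j g_ax V_j'
    //     = Cm*area*1e3/dt V_i + g_mem*erev + I_inj
    for (int i = 0; i < n; ++i) {
      double gm   = gl + gbar[i] * l[i];
      double gtot = gm * 1e6 * area[i];               // S -> uS
      double erev = (gl * e_pas + gbar[i] * l[i] * Eh) / gm;
      double cdt  = Cm * area[i] * 1e3 / dt;          // uF/ms -> uS
      b[i] = cdt + gtot;
      d[i] = cdt * V[i] + gtot * erev;
      a[i] = 0.0; c[i] = 0.0;
    }
    d[0] += Iinj * 1e-3;                              // pA -> nA
    for (int i = 0; i < n - 1; ++i) {
      double gc = g_axial[i] * 1e6;                   // S -> uS
      b[i] += gc; b[i + 1] += gc;
      c[i] = -gc; a[i + 1] = -gc;
    }
    cp[0] = c[0] / b[0]; dp[0] = d[0] / b[0];
    for (int i = 1; i < n; ++i) {
      double m = b[i] - a[i] * cp[i - 1];
      cp[i] = c[i] / m;
      dp[i] = (d[i] - a[i] * dp[i - 1]) / m;
    }
    V[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) V[i] = dp[i] - cp[i] * V[i + 1];
  }
  return vout;
}
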
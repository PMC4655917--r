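// Conductance-based neural mass network: right-hand side and fixed-step RK4.
// State layout, for source s (0..S-1) and population p (0 = spiny stellate,
// 1 = pyramidal, 2 = inhibitory interneuron):
//   x[(s*3+p)*5 + 0] = membrane potential V (mV)
//   x[(s*3+p)*5 + 1] = AMPA conductance g_A
//   x[(s*3+p)*5 + 2] = NMDA conductance g_N
//   x[(s*3+p)*5 + 3] = GABA_A conductance g_G
//   x[(s*3+p)*5 + 4] = KIR conductance g_K
// Units: mV, ms. Conductances are dimensionless scale units.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

namespace {

struct NmmPars {
  int S;
  // channel constants
  double rev_na, rev_cl, rev_k;
  double tau_a, tau_n, tau_g, tau_k;
  // log-scale-applied channel gains (alpha_NA, alpha_CA_NA, alpha_Cl, alpha_KL, alpha_KIR)
  double a_na, a_can, a_cl, a_kl, a_kir;
  // firing sigmoid
  double omega, vthresh;
  // gates
  double kir_half, kir_slope, nmda_c1, nmda_c2;
  // membrane rate constant (1/ms)
  double kappa;
  // intrinsic weights: ss->py, ss->in, in->py, in->ss, py->ss
  double g_sp, g_si, g_ip, g_is, g_ps;
  // extrinsic adjacency (S x S, row = target, col = source), already
  // condition-scaled by the caller
  NumericMatrix A_fwd, A_bwd;
  // exogenous input
  NumericVector Cin;
  double u_onset, u_sd, u_amp;
  // NMDA voltage gate clamped open (diagnostic use)
  bool clamp_nmda;
};

NmmPars unpack(const List& p) {
  NmmPars q;
  q.S = as<int>(p["n_sources"]);
  q.rev_na = as<double>(p["rev_na"]);
  q.rev_cl = as<double>(p["rev_cl"]);
  q.rev_k = as<double>(p["rev_k"]);
  q.tau_a = as<double>(p["tau_a"]);
  q.tau_n = as<double>(p["tau_n"]);
  q.tau_g = as<double>(p["tau_g"]);
  q.tau_k = as<double>(p["tau_k"]);
  q.a_na = as<double>(p["a_na"]);
  q.a_can = as<double>(p["a_can"]);
  q.a_cl = as<double>(p["a_cl"]);
  q.a_kl = as<double>(p["a_kl"]);
  q.a_kir = as<double>(p["a_kir"]);
  q.omega = as<double>(p["omega"]);
  q.vthresh = as<double>(p["vthresh"]);
  q.kir_half = as<double>(p["kir_half"]);
  q.kir_slope = as<double>(p["kir_slope"]);
  q.nmda_c1 = as<double>(p["nmda_c1"]);
  q.nmda_c2 = as<double>(p["nmda_c2"]);
  q.kappa = as<double>(p["kappa"]);
  NumericVector gam = p["gamma"];
  q.g_sp = gam[0]; q.g_si = gam[1]; q.g_ip = gam[2]; q.g_is = gam[3]; q.g_ps = gam[4];
  q.A_fwd = as<NumericMatrix>(p["A_fwd"]);
  q.A_bwd = as<NumericMatrix>(p["A_bwd"]);
  q.Cin = as<NumericVector>(p["C_in"]);
  q.u_onset = as<double>(p["u_onset"]);
  q.u_sd = as<double>(p["u_sd"]);
  q.u_amp = as<double>(p["u_amp"]);
  q.clamp_nmda = as<bool>(p["clamp_nmda"]);
  return q;
}

inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

inline double firing(double V, const NmmPars& q) {
  return sigmoid(std::sqrt(q.omega) * (V - q.vthresh));
}
inline double kir_gate_c(double V, const NmmPars& q) {
  return sigmoid(-(V - q.kir_half) / q.kir_slope);
}
inline double nmda_gate_c(double V, const NmmPars& q) {
  if (q.clamp_nmda) return 1.0;
  return 1.0 / (1.0 + q.nmda_c1 * std::exp(-q.nmda_c2 * V));
}
inline double bump(double t, const NmmPars& q) {
  double z = (t - q.u_onset) / q.u_sd;
  return q.u_amp * std::exp(-0.5 * z * z);
}

// dx for the whole network at time t
void rhs(double t, const double* x, double* dx, const NmmPars& q) {
  const int S = q.S;
  std::vector<double> Hss(S), Hpy(S), Hin(S);
  for (int s = 0; s < S; ++s) {
    Hss[s] = firing(x[(s * 3 + 0) * 5], q);
    Hpy[s] = firing(x[(s * 3 + 1) * 5], q);
    Hin[s] = firing(x[(s * 3 + 2) * 5], q);
  }
  double u = bump(t, q);
  for (int s = 0; s < S; ++s) {
    double ext_f = 0.0, ext_b = 0.0;
    for (int j = 0; j < S; ++j) {
      ext_f += q.A_fwd(s, j) * Hpy[j];
      ext_b += q.A_bwd(s, j) * Hpy[j];
    }
    // excitatory / inhibitory afferent drives per population
    double e[3], inh[3];
    e[0] = q.g_ps * Hpy[s] + ext_f + q.Cin[s] * u;  // stellate
    e[1] = q.g_sp * Hss[s] + ext_b;                 // pyramidal
    e[2] = q.g_si * Hss[s] + ext_b;                 // interneuron
    inh[0] = q.g_is * Hin[s];
    inh[1] = q.g_ip * Hin[s];
    inh[2] = 0.0;
    for (int p = 0; p < 3; ++p) {
      const int b = (s * 3 + p) * 5;
      double V = x[b], gA = x[b + 1], gN = x[b + 2], gG = x[b + 3], gK = x[b + 4];
      dx[b + 1] = (q.a_na * e[p] - gA) / q.tau_a;
      dx[b + 2] = (q.a_can * e[p] - gN) / q.tau_n;
      dx[b + 3] = (q.a_cl * inh[p] - gG) / q.tau_g;
      dx[b + 4] = (q.a_kir - gK) / q.tau_k;
      dx[b] = q.kappa * (gA * (q.rev_na - V) + gN * nmda_gate_c(V, q) * (q.rev_na - V) +
                         gG * (q.rev_cl - V) + gK * kir_gate_c(V, q) * (q.rev_k - V) +
                         q.a_kl * (q.rev_k - V));
    }
  }
}

void rk4_step(double t, double dt, std::vector<double>& x, const NmmPars& q,
              std::vector<double>& k1, std::vector<double>& k2,
              std::vector<double>& k3, std::vector<double>& k4,
              std::vector<double>& tmp) {
  const size_t n = x.size();
  rhs(t, x.data(), k1.data(), q);
  for (size_t i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * dt * k1[i];
  rhs(t + 0.5 * dt, tmp.data(), k2.data(), q);
  for (size_t i = 0; i < n; ++i) tmp[i] = x[i] + 0.5 * dt * k2[i];
  rhs(t + 0.5 * dt, tmp.data(), k3.data(), q);
  for (size_t i = 0; i < n; ++i) tmp[i] = x[i] + dt * k3[i];
  rhs(t + dt, tmp.data(), k4.data(), q);
  for (size_t i = 0; i < n; ++i)
    x[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

}  // namespace

// [[Rcpp::export]]
NumericVector nmm_rhs_cpp(double t, NumericVector x, List pars) {
  NmmPars q = unpack(pars);
  NumericVector dx(x.size());
  rhs(t, REAL(x), REAL(dx), q);
  return dx;
}

// Integrate from x0 over n_steps of size dt starting at t0; sample every
// `sample_every` steps (the initial state is sample 0). Returns a matrix
// (state x samples). Errors out if any |V| exceeds 500 mV.
// [[Rcpp::export]]
NumericMatrix nmm_integrate_cpp(NumericVector x0, List pars, double t0, double dt,
                                int n_steps, int sample_every) {
  NmmPars q = unpack(pars);
  const size_t n = x0.size();
  std::vector<double> x(REAL(x0), REAL(x0) + n);
  std::vector<double> k1(n), k2(n), k3(n), k4(n), tmp(n);
  int n_samples = n_steps / sample_every + 1;
  NumericMatrix out(n, n_samples);
  for (size_t i = 0; i < n; ++i) out(i, 0) = x[i];
  int col = 1;
  for (int s = 1; s <= n_steps; ++s) {
    rk4_step(t0 + (s - 1) * dt, dt, x, q, k1, k2, k3, k4, tmp);
    for (int src = 0; src < q.S * 3; ++src) {
      double V = x[src * 5];
      if (!std::isfinite(V) || std::fabs(V) > 500.0)
        stop("integration blow-up at step %d (|V| > 500 mV or non-finite)", s);
    }
    if (s % sample_every == 0) {
      for (size_t i = 0; i < n; ++i) out(i, col) = x[i];
      ++col;
    }
  }
  return out;
}
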
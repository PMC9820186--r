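#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Fixed-step integrator of the three-population ionic rate model.
//
// The stochastic forcing is a piecewise-constant process on a fixed grid of
// width `noise_dt` (the noise matrix holds one standard-normal draw per
// population per block). At dt == noise_dt this is Euler-Maruyama; at finer
// dt the same realized forcing is integrated deterministically, so
// trajectories converge as dt -> 0 under a fixed seed.
//
// Parameter vector layout (packed by pack_params() on the R side):
//   per population p in {E1, E2, I}, 8 values each starting at 8*p:
//     nu_max, V_theta, k_nu, tau_m, R_in, w_from_E, w_from_I, noise_sigma
//   pump at 24: rho, theta_Na, sigma_Na, theta_K, sigma_K, gamma_electro
//   ions at 30: K_bath, Na_rest, Cl_rest_normal, Cl_rest_high, Cl_out,
//               tau_K, tau_Na, tau_Cl, delta_K, delta_Na, delta_Cl,
//               c_K, RT_F, V_rest
//   syn at 44: tau_D, delta_D, V_norm, tau_ampa, tau_gaba, g_ampa, g_gaba
//   clamp at 51: V_hold (absolute mV)
// Protocol vector: frequency, pulse_width, amp_E1, amp_E2, amp_I_effective,
//   t_start, t_stop (amplitudes in pA, I already scaled by the stimulated
//   fraction).

static inline double sigm(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// [[Rcpp::export(name = ".integrate_network_cpp")]]
NumericMatrix integrate_network_cpp(NumericVector state0,
                                    NumericVector par,
                                    NumericVector proto,
                                    double duration,
                                    double dt,
                                    NumericMatrix noise,
                                    double noise_dt,
                                    int thin) {
  const double rho = par[24], thNa = par[25], sgNa = par[26],
               thK = par[27], sgK = par[28], gamma = par[29];
  const double K_bath = par[30], Na_rest = par[31], Cl_rn = par[32],
               Cl_rh = par[33], Cl_out = par[34], tau_K = par[35],
               tau_Na = par[36], tau_Cl = par[37], dK_g = par[38],
               dNa_g = par[39], dCl_g = par[40], c_K = par[41],
               RT_F = par[42], V_rest = par[43];
  const double tau_D = par[44], delta_D = par[45], V_norm = par[46],
               tau_ampa = par[47], tau_gaba = par[48], g_ampa = par[49],
               g_gaba = par[50], V_hold = par[51];
  const double freq = proto[0], width = proto[1], t_start = proto[5],
               t_stop = proto[6];
  const double amp[3] = {proto[2], proto[3], proto[4]};
  const double period = 1.0 / freq;

  const long n_steps = (long)std::lround(duration / dt);
  const long n_blocks = noise.ncol();
  const long n_rec = n_steps / thin + 1;
  NumericMatrix out(n_rec, 14);

  double V[3] = {state0[0], state0[1], state0[2]};
  double K = state0[3], Na = state0[4];
  double Cl[2] = {state0[5], state0[6]};
  double xD = state0[7];
  double aA = 0.0, aG = 0.0;  // filtered presynaptic rates (clamp observable)

  const double E_gaba_I = RT_F * std::log(Cl_rn / Cl_out) - V_rest;

  long irec = 0;
  for (long step = 0; step <= n_steps; ++step) {
    const double t = step * dt;

    // rates and fluxes at the current state
    double nu[3];
    for (int p = 0; p < 3; ++p) {
      nu[p] = par[8 * p] * sigm((V[p] - par[8 * p + 1]) / par[8 * p + 2]);
    }
    const double nu_E = 0.5 * (nu[0] + nu[1]);
    const double f = rho * sigm((Na - thNa) / sgNa) * sigm((K - thK) / sgK);
    const double E_gaba_abs1 = RT_F * std::log(Cl[0] / Cl_out);
    const double I_vc = g_ampa * aA * V_hold +
                        g_gaba * aG * (V_hold - E_gaba_abs1);

    if (step % thin == 0) {
      out(irec, 0) = t;
      out(irec, 1) = V[0]; out(irec, 2) = V[1]; out(irec, 3) = V[2];
      out(irec, 4) = K; out(irec, 5) = Na;
      out(irec, 6) = Cl[0]; out(irec, 7) = Cl[1];
      out(irec, 8) = xD;
      out(irec, 9) = nu[0]; out(irec, 10) = nu[1]; out(irec, 11) = nu[2];
      out(irec, 12) = f;
      out(irec, 13) = I_vc;
      ++irec;
    }
    if (step == n_steps) break;

    // stimulus (pA) during the active pulse window
    double I_stim[3] = {0.0, 0.0, 0.0};
    if (t >= t_start && t < t_stop) {
      const double rel = t - t_start;
      const double phase = rel - period * std::floor(rel / period);
      if (phase < width) {
        I_stim[0] = amp[0]; I_stim[1] = amp[1]; I_stim[2] = amp[2];
      }
    }

    const double uK = c_K * std::log(K / K_bath);
    long jb = (long)(t / noise_dt);
    if (jb >= n_blocks) jb = n_blocks - 1;

    double dV[3];
    for (int p = 0; p < 3; ++p) {
      const double tau_m = par[8 * p + 3], R_in = par[8 * p + 4],
                   w_E = par[8 * p + 5], w_I = par[8 * p + 6],
                   sig = par[8 * p + 7];
      const double E_g = (p == 2) ? E_gaba_I
                                  : RT_F * std::log(Cl[p] / Cl_out) - V_rest;
      const double u_syn =
          (p == 2 ? w_E * nu_E : w_E * xD * nu_E) +
          w_I * nu[2] * (V[p] - E_g) / V_norm;
      const double eta = sig * std::sqrt(tau_m / noise_dt) * noise(p, jb);
      dV[p] = (-V[p] + uK + u_syn + R_in * I_stim[p] / 1000.0 -
               gamma * f + eta) / tau_m;
    }
    const double dK = (K_bath - K) / tau_K + dK_g * nu_E - 2.0 * f;
    const double dNa = (Na_rest - Na) / tau_Na + dNa_g * nu_E - 3.0 * f;
    double dCl[2];
    for (int p = 0; p < 2; ++p) {
      const double E_g = RT_F * std::log(Cl[p] / Cl_out) - V_rest;
      const double drive = V[p] - E_g;
      const double Cl_rest = (p == 0) ? Cl_rn : Cl_rh;
      dCl[p] = (Cl_rest - Cl[p]) / tau_Cl +
               dCl_g * nu[2] * (drive > 0.0 ? drive : 0.0);
    }
    const double dxD = (1.0 - xD) / tau_D - delta_D * xD * nu_E;
    const double daA = (xD * nu_E - aA) / tau_ampa;
    const double daG = (nu[2] - aG) / tau_gaba;

    for (int p = 0; p < 3; ++p) V[p] += dt * dV[p];
    K += dt * dK; Na += dt * dNa;
    Cl[0] += dt * dCl[0]; Cl[1] += dt * dCl[1];
    xD += dt * dxD;
    if (xD < 0.0) xD = 0.0;
    if (xD > 1.0) xD = 1.0;
    aA += dt * daA; aG += dt * daG;

    // instability guard: name the first offending channel and time
    const char *bad = nullptr;
    if (std::abs(V[0]) > 500.0) bad = "V_E1";
    else if (std::abs(V[1]) > 500.0) bad = "V_E2";
    else if (std::abs(V[2]) > 500.0) bad = "V_I";
    else if (K <= 0.0) bad = "K_o";
    else if (Na <= 0.0) bad = "Na_i";
    else if (Cl[0] <= 0.0) bad = "Cl_E1";
    else if (Cl[1] <= 0.0) bad = "Cl_E2";
    if (bad != nullptr) {
      stop("integration unstable: channel %s at t = %.3f s", bad,
           t + dt);
    }
  }
  return out;
}
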
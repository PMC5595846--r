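// Closed-loop digital twin of the load-controlled micro-indenter.
//
// Per sample: (1) the protocol supplies a load setpoint (constant during
// hold, sinusoidal during sweep segments); (2) a discrete PI controller on
// the measured-load error drives the piezo velocity, with an adaptive
// single-frequency feed-forward phasor during oscillation segments;
// (3) an optional stick-slip transmission maps piezo to probe position;
// (4) the quasi-static cantilever/sample equilibrium k*d = F_sample(h),
// h = z_probe - d - z_surface, is solved by safeguarded Newton, where
// F_sample applies the viscoelastic memory kernel (exact per-step
// exponential update of each Maxwell branch) to the Hertzian
// pseudo-strain u = h^(3/2):  F = C * (G o u),  C = 8 sqrt(R) / (3 (1-nu)).
//
// The kernel update is linear in the strain increment, so within a step
// F_sample(d) = C * (alpha + beta * (u(d) - u_prev)) with
// beta = G_e + sum_j G_j tau_j (1 - e^(-dt/tau_j)) / dt + eta/dt and
// alpha = G_e u_prev + sum_j sigma_j e^(-dt/tau_j); the equilibrium
// equation is monotone and has a unique root.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List twin_simulate_cpp(double dt,
                       IntegerVector seg_type, IntegerVector seg_n,
                       NumericVector seg_freq, NumericVector seg_amp,
                       NumericVector seg_Hre, NumericVector seg_Him,
                       double Ge, double eta,
                       NumericVector Gb, NumericVector taub,
                       double Cpref, double k, double z_surface,
                       double approach_speed, double retract_speed,
                       double static_load, double thr_force, int debounce,
                       double Kp, double Ki, double integ_clamp,
                       NumericVector noise, NumericVector drift,
                       bool rigid, double sens,
                       bool ss_on, double ss_vcrit, double ss_dwell,
                       double ss_slip, double piezo_range)
{
  const int nseg = seg_type.size();
  R_xlen_t ntot = 0;
  for (int s = 0; s < nseg; s++) ntot += seg_n[s];
  if (noise.size() != ntot || drift.size() != ntot)
    stop("internal: noise/drift length mismatch");

  NumericVector zp_out(ntot), dmeas_out(ntot), dtrue_out(ntot);

  const int nb = Gb.size();
  std::vector<double> Ei(nb), gam(nb), sig(nb, 0.0);
  for (int j = 0; j < nb; j++) {
    Ei[j] = std::exp(-dt / taub[j]);
    gam[j] = Gb[j] * taub[j] * (1.0 - Ei[j]) / dt;
  }
  double beta = Ge + eta / dt;
  for (int j = 0; j < nb; j++) beta += gam[j];

  double u_prev = 0.0;      // pseudo-strain h^(3/2) at the contact
  double z_base = 0.0;      // controller piezo baseline
  double z_probe = 0.0;     // probe-side position (after transmission)
  double zp_prev = 0.0;
  double d_true = 0.0;
  double F_meas = 0.0;
  double integ = 0.0;
  bool contacted = false;
  bool has_approach = false;
  int cnt = 0;
  R_xlen_t contact_idx = -1;
  double dwell = 0.0;
  bool stuck = false;

  R_xlen_t g = 0;
  for (int s = 0; s < nseg; s++) {
    const int type = seg_type[s];
    const double f = seg_freq[s], A = seg_amp[s];
    const double w = 2.0 * M_PI * f;
    if (type == 0) has_approach = true;

    // adaptive feed-forward phasor (a*sin + b*cos) for oscillation segments,
    // initialized from the linearized plant guess H and corrected once per
    // period from the measured single-frequency load amplitude
    double za = 0.0, zb = 0.0, z0mag = 0.0;
    R_xlen_t P = 0, bi = 0;
    double accS = 0.0, accC = 0.0, accM = 0.0, sS = 0.0, sC = 0.0;
    if (type == 2) {
      const double Hre = seg_Hre[s], Him = seg_Him[s];
      const double H2 = Hre * Hre + Him * Him;
      za = A * Hre / H2;
      zb = -A * Him / H2;
      z0mag = std::sqrt(za * za + zb * zb);
      P = (R_xlen_t) std::lround(1.0 / (f * dt));
      if (P < 4) P = 4;
    }

    for (R_xlen_t i = 0; i < seg_n[s]; i++, g++) {
      const double tseg = (double) i * dt;
      double z_p;
      if (type == 0 && !contacted) {           // approach ramp
        z_base += approach_speed * dt;
        z_p = z_base;
      } else if (type == 3) {                  // retract ramp
        z_base -= retract_speed * dt;
        z_p = z_base;
      } else {                                 // load regulation
        const double Fset = (type == 2)
          ? static_load + A * std::sin(w * tseg) : static_load;
        const double err = Fset - F_meas;
        // the integrator (which by the end of the hold has learned the
        // drift-compensation velocity) is frozen during oscillation
        // segments: its pole would resonate with sweep frequencies near
        // sqrt(g*Ki) on compliant samples; the adaptive feed-forward
        // tracks the sinusoid instead
        if (type != 2) {
          integ += err * dt;
          if (integ > integ_clamp) integ = integ_clamp;
          if (integ < -integ_clamp) integ = -integ_clamp;
        }
        z_base += (Kp * err + Ki * integ) * dt;
        z_p = z_base;
        if (type == 2)
          z_p += za * std::sin(w * tseg) + zb * std::cos(w * tseg);
      }
      if (std::fabs(z_p) > piezo_range)
        stop("protocol fault: piezo travel range exceeded");

      // stick-slip transmission (needle-shaft friction); static friction
      // engages only after the commanded speed stays below ss_vcrit for
      // ss_dwell seconds, and releases after ss_slip of accumulated play
      if (ss_on) {
        const double v_cmd = (z_p - zp_prev) / dt;
        if (std::fabs(v_cmd) < ss_vcrit) dwell += dt;
        else { dwell = 0.0; stuck = false; }
        if (dwell >= ss_dwell) stuck = true;
        if (stuck) {
          if (std::fabs(z_p - z_probe) > ss_slip) {
            z_probe = z_p; dwell = 0.0; stuck = false;
          }
        } else {
          z_probe = z_p;
        }
      } else {
        z_probe = z_p;
      }
      zp_prev = z_p;

      // quasi-static cantilever/sample equilibrium
      const double h_avail = z_probe - z_surface;
      if (rigid) {
        d_true = h_avail > 0.0 ? h_avail : 0.0;
      } else if (h_avail <= 0.0) {
        d_true = 0.0;
        for (int j = 0; j < nb; j++) sig[j] *= Ei[j];  // free relaxation
      } else {
        double sigdec = 0.0;
        for (int j = 0; j < nb; j++) sigdec += sig[j] * Ei[j];
        const double alpha = Ge * u_prev + sigdec;
        // root of k d = C (alpha + beta (u(d) - u_prev)) on [0, h_avail]
        double lo = 0.0, hi = h_avail;
        const double u_at0 = h_avail * std::sqrt(h_avail);
        const double Fs_at0 = Cpref * (alpha + beta * (u_at0 - u_prev));
        if (Fs_at0 <= 0.0) {
          // contact cannot sustain compression: separated
          d_true = 0.0;
          for (int j = 0; j < nb; j++) sig[j] *= Ei[j];
        } else {
          double d = d_true;
          if (d <= lo || d >= hi) d = 0.5 * hi;
          for (int it = 0; it < 80; it++) {
            double h = h_avail - d;
            if (h < 0) h = 0;
            const double u = h * std::sqrt(h);
            const double gv = k * d - Cpref * (alpha + beta * (u - u_prev));
            if (gv > 0) hi = d; else lo = d;
            const double gp = k + Cpref * beta * 1.5 * std::sqrt(h);
            double dn = d - gv / gp;
            if (dn <= lo || dn >= hi) dn = 0.5 * (lo + hi);
            if (std::fabs(dn - d) < 1e-18 + 1e-13 * std::fabs(d)) { d = dn; break; }
            d = dn;
          }
          d_true = d;
          double h = h_avail - d;
          if (h < 0) h = 0;
          const double u_new = h * std::sqrt(h);
          const double du = u_new - u_prev;
          for (int j = 0; j < nb; j++) sig[j] = sig[j] * Ei[j] + gam[j] * du;
          u_prev = u_new;
        }
      }

      const double d_m = sens * (d_true + noise[g] + drift[g]);
      F_meas = k * d_m;
      zp_out[g] = z_p;
      dmeas_out[g] = d_m;
      dtrue_out[g] = d_true;

      if (type == 0 && !contacted) {
        if (F_meas > thr_force) {
          cnt++;
          if (cnt >= debounce) { contacted = true; contact_idx = g - debounce + 1; }
        } else cnt = 0;
      }

      if (type == 2) {
        accS += F_meas * std::sin(w * tseg);
        accC += F_meas * std::cos(w * tseg);
        accM += F_meas;
        sS += std::sin(w * tseg);
        sC += std::cos(w * tseg);
        bi++;
        if (bi == P) {
          const double mn = accM / (double) P;
          const double a = 2.0 * (accS - mn * sS) / (double) P;
          const double b = 2.0 * (accC - mn * sC) / (double) P;
          const double f2 = a * a + b * b;
          if (std::sqrt(f2) < 0.05 * A) {
            za *= 2.0; zb *= 2.0;
          } else {
            const double mre = A * a / f2, mim = -A * b / f2;
            const double nza = za * mre - zb * mim;
            const double nzb = za * mim + zb * mre;
            za = nza; zb = nzb;
          }
          const double zm = std::sqrt(za * za + zb * zb);
          if (zm > 5.0 * z0mag) { za *= 5.0 * z0mag / zm; zb *= 5.0 * z0mag / zm; }
          if (zm > 0 && zm < 0.2 * z0mag) { za *= 0.2 * z0mag / zm; zb *= 0.2 * z0mag / zm; }
          accS = accC = accM = sS = sC = 0.0;
          bi = 0;
        }
      }
    }
  }

  if (has_approach && !contacted)
    stop("simulation fault: no contact detected during the approach segment");

  return List::create(_["piezo_position"] = zp_out,
                      _["deflection"] = dmeas_out,
                      _["deflection_true"] = dtrue_out,
                      _["contact_index"] = (double) (contact_idx + 1));
}
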
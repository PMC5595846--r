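# Independent oracles and shared fixtures for the test suite.

# single-bin discrete Fourier projection at a known frequency (the
# classical lock-in estimate), independent of the least-squares path
dft_single_bin <- function(x, f, fs) {
  n <- length(x)
  t <- (seq_len(n) - 1) / fs
  a <- 2 * sum(x * sin(2 * pi * f * t)) / n
  b <- 2 * sum(x * cos(2 * pi * f * t)) / n
  list(amplitude = sqrt(a^2 + b^2), phase = atan2(b, a))
}

# ground-truth sample models spanning the soft-tissue-relevant range
# (roughly 1-50 kPa storage), with static loads an operator would choose
# to keep the static depth within the geometric bounds of the probe
truth_models <- function() {
  list(
    soft_sls = list(
      model = rheology_model("standard_linear_solid",
                             G_e = 2e3, G = 2e3, tau = 0.1),
      static_load = 25e-6),
    pdms_sls = list(
      model = rheology_model("standard_linear_solid",
                             G_e = 20e3, G = 10e3, tau = 0.03),
      static_load = 300e-6),
    kelvin_voigt = list(
      model = rheology_model("kelvin_voigt", G_e = 5e3, eta = 30),
      static_load = 60e-6),
    gen_maxwell = list(
      model = rheology_model("generalized_maxwell", G_e = 30e3,
                             G = c(15e3, 10e3), tau = c(0.5, 0.02)),
      static_load = 300e-6))
}

quiet_probe <- function() probe_config(deflection_noise_rms = 0, drift_rate = 0)

# steady-state complex response of the time-domain kernel to a sinusoidal
# strain, extracted by least squares after discarding the settling portion
kernel_sinusoid_response <- function(model, f, dt, n_settle_periods = 3,
                                     n_fit_periods = 3, eps1 = 1e-3) {
  tau_max <- if (length(model$tau)) max(model$tau) else 0
  settle <- max(n_settle_periods / f, 5 * tau_max)
  n_settle <- ceiling(settle / dt)
  n_fit <- round(n_fit_periods / (f * dt))
  t <- (seq_len(n_settle + n_fit) - 1) * dt
  strain <- eps1 * sin(2 * pi * f * t)
  stress <- simulate_stress(model, strain, dt)
  keep <- (n_settle + 1):length(t)
  fit_in <- extract_sinusoid(strain[keep], f, t = t[keep])
  fit_out <- extract_sinusoid(stress[keep], f, t = t[keep])
  list(gain = fit_out$amplitude / fit_in$amplitude,
       phase = fit_out$phase - fit_in$phase)
}
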
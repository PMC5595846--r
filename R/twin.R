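#' Ferrule-top probe configuration
#'
#' @param spring_constant cantilever spring constant k (N/m); fabricated
#'   probes of this type fall in the 60-70 N/m band.
#' @param bead_radius spherical tip radius (m); 150 um fits the 18G
#'   needle lumen.
#' @param deflection_noise_rms RMS of the additive deflection readout
#'   noise (m).
#' @param drift_rate slow linear deflection drift (m/s).
#' @param sensitivity_scale multiplicative deflection calibration factor
#'   (1 for a perfectly calibrated readout); recoverable by
#'   [calibrate_on_glass()].
#' @return object of class `probe_config`.
#' @export
probe_config <- function(spring_constant = 65, bead_radius = 150e-6,
                         deflection_noise_rms = 2e-9, drift_rate = 5e-11,
                         sensitivity_scale = 1) {
  stopifnot(spring_constant > 0, bead_radius > 0,
            deflection_noise_rms >= 0, drift_rate >= 0,
            sensitivity_scale > 0)
  structure(list(spring_constant = spring_constant, bead_radius = bead_radius,
                 deflection_noise_rms = deflection_noise_rms,
                 drift_rate = drift_rate,
                 sensitivity_scale = sensitivity_scale),
            class = "probe_config")
}

#' Oscillatory load-sweep measurement protocol
#'
#' Defaults reproduce the full-band sweep: a ~300 uN static load held for
#' at least 60 s, then a ~10 uN load oscillation at 15 log-spaced
#' frequencies from 0.05 to 10 Hz, 5 periods each, followed by a 100 um
#' retraction. `mode = "np_mode"` switches to the reduced in-situ sweep
#' (5 frequencies, 0.5-10 Hz) used for confined, hydrated tissue where
#' measurement time must be short.
#'
#' @param mode `"full_band"` (15 frequencies, 0.05-10 Hz) or `"np_mode"`
#'   (5 frequencies, 0.5-10 Hz). Presets fill `f_min`, `f_max`,
#'   `n_frequencies` when those are NULL.
#' @param static_load static load setpoint (N).
#' @param oscillation_amplitude load oscillation amplitude (N); default
#'   `static_load / 30`, preserving the protocol's 300:10 ratio so the
#'   relative indentation oscillation stays in the linear regime.
#' @param f_min,f_max sweep band limits (Hz).
#' @param n_frequencies number of log-spaced sweep frequencies (>= 2).
#' @param periods_per_frequency oscillation periods per frequency (>= 1).
#' @param hold_time static-load hold before the sweep (s).
#' @param retract_distance retraction after the sweep (m).
#' @param sample_rate recording sample rate (Hz).
#' @param approach_speed,approach_gap approach ramp speed (m/s) and free
#'   gap between the starting tip position and the surface (m).
#' @param retract_speed retraction speed (m/s).
#' @param contact_threshold deflection threshold for contact detection
#'   (m); default 5x the probe's deflection noise RMS with a 10 pm floor.
#' @param debounce_time persistence window for contact detection (s).
#' @return object of class `sweep_protocol`.
#' @export
sweep_protocol <- function(mode = c("full_band", "np_mode"),
                           static_load = 300e-6,
                           oscillation_amplitude = static_load / 30,
                           f_min = NULL, f_max = NULL, n_frequencies = NULL,
                           periods_per_frequency = 5,
                           hold_time = 60,
                           retract_distance = 100e-6,
                           sample_rate = 1000,
                           approach_speed = 10e-6, approach_gap = 20e-6,
                           retract_speed = 20e-6,
                           contact_threshold = NULL,
                           debounce_time = 0.02) {
  mode <- match.arg(mode)
  preset <- switch(mode,
                   full_band = list(f_min = 0.05, f_max = 10, n = 15L),
                   np_mode = list(f_min = 0.5, f_max = 10, n = 5L))
  if (is.null(f_min)) f_min <- preset$f_min
  if (is.null(f_max)) f_max <- preset$f_max
  if (is.null(n_frequencies)) n_frequencies <- preset$n
  n_frequencies <- as.integer(n_frequencies)
  if (is.na(n_frequencies) || n_frequencies < 2L)
    stop("sweep_protocol: 'n_frequencies' must be >= 2", call. = FALSE)
  stopifnot(f_min > 0, f_min < f_max,
            static_load > 0, oscillation_amplitude > 0,
            oscillation_amplitude < static_load,
            periods_per_frequency >= 1, hold_time >= 0,
            retract_distance > 0, sample_rate > 0,
            approach_speed > 0, approach_gap > 0, retract_speed > 0,
            debounce_time >= 0)
  if (sample_rate < 20 * f_max)
    stop("sweep_protocol: 'sample_rate' must resolve the fastest oscillation (>= 20 f_max)",
         call. = FALSE)
  structure(list(mode = mode, static_load = static_load,
                 oscillation_amplitude = oscillation_amplitude,
                 f_min = f_min, f_max = f_max,
                 n_frequencies = n_frequencies,
                 periods_per_frequency = as.integer(periods_per_frequency),
                 hold_time = hold_time,
                 retract_distance = retract_distance,
                 sample_rate = sample_rate,
                 approach_speed = approach_speed,
                 approach_gap = approach_gap,
                 retract_speed = retract_speed,
                 contact_threshold = contact_threshold,
                 debounce_time = debounce_time),
            class = "sweep_protocol")
}

#' Log-spaced sweep frequency grid
#'
#' @param protocol a [sweep_protocol()].
#' @return strictly increasing vector of `n_frequencies` values,
#'   log-spaced and inclusive of both band limits.
#' @export
frequency_grid <- function(protocol) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  10^seq(log10(protocol$f_min), log10(protocol$f_max),
         length.out = protocol$n_frequencies)
}

#' Stick-slip needle-friction disturbance configuration
#'
#' Optional disturbance on the piezo-to-probe transmission emulating
#' friction of the probe in the needle shaft after piercing stiff tissue:
#' when the commanded speed stays below `v_crit` for longer than
#' `dwell_time`, static friction engages and the probe sticks until
#' `slip_distance` of play has accumulated, then slips. At sweep
#' frequencies whose peak piezo speed exceeds `v_crit` the transmission
#' is clean; at the lowest frequencies the waveform degrades into a
#' staircase and the phase estimate becomes unreliable. Off by default.
#'
#' @param enabled logical.
#' @param v_crit speed below which static friction can engage (m/s).
#' @param dwell_time time below `v_crit` needed to engage (s).
#' @param slip_distance accumulated play released per slip event (m).
#' @return object of class `stick_slip_config`.
#' @export
stick_slip_config <- function(enabled = FALSE, v_crit = 3e-6,
                              dwell_time = 0.5, slip_distance = 0.2e-6) {
  stopifnot(is.logical(enabled), v_crit > 0, dwell_time >= 0,
            slip_distance > 0)
  structure(list(enabled = isTRUE(enabled), v_crit = v_crit,
                 dwell_time = dwell_time, slip_distance = slip_distance),
            class = "stick_slip_config")
}

# deterministic per-sample protocol segmentation (label, length, frequency,
# force amplitude); the approach window is sized to cover the free gap plus
# the load ramp with margin, so segment boundaries depend only on the protocol
protocol_segments <- function(protocol) {
  fs <- protocol$sample_rate
  freqs <- frequency_grid(protocol)
  approach_t <- protocol$approach_gap / protocol$approach_speed + 8
  seg <- data.frame(
    label = c("approach", "hold",
              sprintf("oscillation@%.10gHz", freqs), "retract"),
    type = c(0L, 1L, rep(2L, length(freqs)), 3L),
    n = c(round(approach_t * fs), round(protocol$hold_time * fs),
          ceiling(protocol$periods_per_frequency / freqs * fs),
          round(protocol$retract_distance / protocol$retract_speed * fs)),
    frequency = c(0, 0, freqs, 0),
    amplitude = c(0, 0, rep(protocol$oscillation_amplitude, length(freqs)), 0),
    stringsAsFactors = FALSE)
  seg$n <- as.integer(seg$n)
  seg
}

contact_threshold_force <- function(probe, protocol) {
  thr_d <- protocol$contact_threshold
  if (is.null(thr_d)) thr_d <- max(5 * probe$deflection_noise_rms, 1e-11)
  probe$spring_constant * thr_d
}

#' Simulate a full load-controlled indentation measurement
#'
#' Executes the measurement protocol in closed loop on a synthetic
#' viscoelastic half-space: constant-speed approach, debounced contact
#' detection, proportional-integral load control to the static setpoint,
#' a hold for stress dissipation, one oscillation segment per sweep
#' frequency (sinusoidal load setpoint tracked by a per-period adaptive
#' feed-forward), and retraction. The cantilever is quasi-static
#' (`F = k d`; the sweep band lies far below any cantilever resonance)
#' and the sample responds through the viscoelastic Hertzian memory
#' kernel. Additive deflection noise and slow drift are applied to the
#' recorded (and feedback-sensed) deflection. The same seed and
#' configuration give a bit-identical recording.
#'
#' @param model a time-domain-capable [rheology_model()] (ignored when
#'   `rigid = TRUE`).
#' @param probe a [probe_config()].
#' @param contact a [contact_config()]; defaults to the probe's bead
#'   radius with nu = 0.5.
#' @param protocol a [sweep_protocol()].
#' @param seed integer seed for the measurement noise.
#' @param rigid simulate an infinitely stiff substrate (glass), used for
#'   the calibration procedure; indentation is zero and piezo motion
#'   converts one-to-one into deflection.
#' @param stick_slip a [stick_slip_config()].
#' @param fidelity `"deflection"` records the demodulated deflection
#'   directly; `"raw_intensity"` additionally synthesizes the
#'   wavelength-modulated Fabry-Perot intensity (requires a sample rate
#'   of at least 10x the cavity modulation frequency) and stores it as
#'   the recorded channel.
#' @param cavity a [cavity_config()], used only for `"raw_intensity"`.
#' @param control optional list with PI gains `Kp` (m s^-1 N^-1) and
#'   `Ki` (m s^-2 N^-1).
#' @return object of class `recording`: a list with `data` (data frame
#'   with columns `time`, `piezo_position`, `deflection`, `load`,
#'   `segment_label`, plus `intensity` at raw fidelity) and `meta`.
#' @export
simulate_measurement <- function(model, probe = probe_config(),
                                 contact = contact_config(probe$bead_radius),
                                 protocol = sweep_protocol(),
                                 seed = 1L,
                                 rigid = FALSE,
                                 stick_slip = stick_slip_config(),
                                 fidelity = c("deflection", "raw_intensity"),
                                 cavity = cavity_config(),
                                 control = list(Kp = 0.2, Ki = 1.0)) {
  fidelity <- match.arg(fidelity)
  stopifnot(inherits(probe, "probe_config"),
            inherits(contact, "contact_config"),
            inherits(protocol, "sweep_protocol"),
            inherits(stick_slip, "stick_slip_config"))
  if (!rigid) {
    stopifnot(inherits(model, "rheology_model"))
    if (model$kind == "springpot")
      stop("simulate_measurement: springpot is frequency-domain only and cannot be simulated",
           call. = FALSE)
  }
  seed <- as.integer(seed)
  seg <- protocol_segments(protocol)
  n <- sum(seg$n)
  dt <- 1 / protocol$sample_rate
  k <- probe$spring_constant
  nu <- contact$poisson_ratio
  cpref <- 8 * sqrt(contact$bead_radius) / (3 * (1 - nu))

  # linearized plant guess F/z at each sweep frequency for the controller's
  # feed-forward initialization (refined per period from the measurement)
  if (rigid) {
    H <- rep(complex(real = k, imaginary = 0), nrow(seg))
  } else {
    h0_est <- (protocol$static_load / (cpref * equilibrium_modulus(model)))^(2 / 3)
    gstar <- complex_modulus_value(model, pmax(seg$frequency, 1e-12))
    S <- 1.5 * cpref * sqrt(h0_est) * gstar
    H <- k * S / (k + S)
  }

  set.seed(seed)
  noise <- if (probe$deflection_noise_rms > 0)
    rnorm(n, sd = probe$deflection_noise_rms) else numeric(n)
  tgrid <- (seq_len(n) - 1) * dt
  drift <- probe$drift_rate * tgrid

  res <- twin_simulate_cpp(
    dt = dt,
    seg_type = seg$type, seg_n = seg$n,
    seg_freq = seg$frequency, seg_amp = seg$amplitude,
    seg_Hre = Re(H), seg_Him = Im(H),
    Ge = if (rigid) 0 else model$G_e,
    eta = if (rigid) 0 else model$eta,
    Gb = if (rigid) numeric(0) else model$G,
    taub = if (rigid) numeric(0) else model$tau,
    Cpref = cpref, k = k, z_surface = protocol$approach_gap,
    approach_speed = protocol$approach_speed,
    retract_speed = protocol$retract_speed,
    static_load = protocol$static_load,
    thr_force = contact_threshold_force(probe, protocol),
    debounce = max(1L, as.integer(round(protocol$debounce_time *
                                          protocol$sample_rate))),
    Kp = control$Kp, Ki = control$Ki,
    integ_clamp = protocol$static_load,
    noise = noise, drift = drift,
    rigid = rigid, sens = probe$sensitivity_scale,
    ss_on = stick_slip$enabled, ss_vcrit = stick_slip$v_crit,
    ss_dwell = stick_slip$dwell_time, ss_slip = stick_slip$slip_distance,
    piezo_range = 500e-6)

  ci <- res$contact_index
  thr_f <- contact_threshold_force(probe, protocol)
  z_contact <- res$piezo_position[ci] - thr_f / k

  dat <- data.frame(
    time = tgrid,
    piezo_position = res$piezo_position,
    deflection = res$deflection,
    load = k * res$deflection,
    segment_label = rep(seg$label, seg$n),
    stringsAsFactors = FALSE)

  meta <- list(probe = unclass(probe), contact = unclass(contact),
               protocol = unclass(protocol)[!vapply(unclass(protocol), is.null, TRUE)],
               model = if (rigid) list(kind = "rigid") else unclass(model),
               stick_slip = unclass(stick_slip),
               seed = seed, rigid = rigid, fidelity = fidelity,
               signal = "deflection",
               z_contact = z_contact,
               z_surface_true = protocol$approach_gap,
               contact_index = as.integer(ci))

  if (fidelity == "raw_intensity") {
    stopifnot(inherits(cavity, "cavity_config"))
    if (protocol$sample_rate < 10 * cavity$modulation_frequency)
      stop("simulate_measurement: raw_intensity fidelity requires sample_rate >= 10x the cavity modulation frequency",
           call. = FALSE)
    dat$intensity <- fringe_intensity(res$deflection, cavity, t = tgrid)
    meta$signal <- "intensity"
    meta$cavity <- unclass(cavity)
  }

  rec <- list(data = dat, meta = meta)
  class(rec) <- "recording"
  rec
}

#' @export
print.recording <- function(x, ...) {
  n <- nrow(x$data)
  cat("<recording>", n, "samples @", x$meta$protocol$sample_rate, "Hz,",
      "model:", x$meta$model$kind, "\n")
  segs <- rle(x$data$segment_label)
  cat("  segments:", paste(segs$values, collapse = " | "), "\n")
  cat("  seed:", x$meta$seed, " z_contact:",
      format(x$meta$z_contact, digits = 4), "m\n")
  invisible(x)
}

#' Detect the contact point in the approach segment
#'
#' Scans the approach segment for the first sample where the load exceeds
#' the threshold persistently over the debounce window; isolated spikes
#' shorter than the window (e.g. premature contact with lumen
#' contamination) are rejected. The contact piezo position is the
#' position at the crossing, extrapolated back by `threshold / k`.
#'
#' @param recording a `recording`.
#' @param threshold force threshold (N); default 5x the recorded
#'   deflection noise RMS times k, with a floor.
#' @param debounce_time persistence window (s).
#' @return list with `index` (sample index in the recording),
#'   `z_contact` (m) and `time` (s).
#' @export
detect_contact <- function(recording, threshold = NULL, debounce_time = 0.02) {
  stopifnot(inherits(recording, "recording"))
  dat <- recording$data
  app <- which(dat$segment_label == "approach")
  if (!length(app))
    stop("detect_contact: recording has no approach segment", call. = FALSE)
  k <- recording$meta$probe$spring_constant
  fs <- recording$meta$protocol$sample_rate
  if (is.null(threshold))
    threshold <- k * max(5 * recording$meta$probe$deflection_noise_rms, 1e-11)
  w <- max(1L, as.integer(round(debounce_time * fs)))
  above <- dat$load[app] > threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  hit <- which(r$values & r$lengths >= w)
  if (!length(hit))
    stop("detect_contact: no persistent load crossing above threshold (no contact)",
         call. = FALSE)
  i0 <- app[ends[hit[1L]] - r$lengths[hit[1L]] + 1L]
  list(index = i0,
       z_contact = dat$piezo_position[i0] - threshold / k,
       time = dat$time[i0])
}

#' Calibrate deflection sensitivity on a rigid substrate
#'
#' On glass the indentation is zero, so deflection tracks piezo position
#' one-to-one in the contact region; a linear fit of deflection against
#' piezo position recovers the sensitivity scale (ideal 1.0) and the
#' geometric contact offset. A slope far from 1 signals an unusable
#' probe (to be discarded and replaced).
#'
#' @param recording a `recording` made with `rigid = TRUE`.
#' @param slope_tolerance maximum |scale - 1| before the probe is
#'   rejected.
#' @return list with `scale`, `offset` (the contact piezo position
#'   implied by the fit, m) and `ok` (FALSE triggers probe rejection).
#' @export
calibrate_on_glass <- function(recording, slope_tolerance = 0.1) {
  stopifnot(inherits(recording, "recording"))
  if (!isTRUE(recording$meta$rigid))
    warning("calibrate_on_glass: recording was not made with the rigid-sample flag")
  dat <- recording$data
  F0 <- recording$meta$protocol$static_load
  sel <- which(dat$segment_label == "approach" &
                 dat$load > 0.1 * F0 & dat$load < 0.9 * F0)
  if (length(sel) < 10L)
    stop("calibrate_on_glass: not enough loading-ramp samples in the contact region",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, dat$piezo_position[sel]), dat$deflection[sel])
  scale <- unname(fit$coefficients[2L])
  offset <- unname(-fit$coefficients[1L] / scale)
  ok <- abs(scale - 1) <= slope_tolerance
  if (!ok)
    warning("calibrate_on_glass: sensitivity scale ", signif(scale, 4),
            " outside tolerance; probe should be discarded and replaced")
  list(scale = scale, offset = offset, ok = ok)
}
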
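#' Fiber-cantilever Fabry-Perot cavity configuration
#'
#' Low-finesse two-beam cavity between the cleaved fiber facet and the
#' cantilever. The reflected intensity is
#' `I = I0 [1 + V cos(4 pi (L0 - d) / lambda_t)]`, periodic in the
#' deflection `d` with period `lambda/2`. A small high-frequency
#' wavelength modulation (depth `modulation_depth` at
#' `modulation_frequency`) provides the quadrature components used for
#' lock-in demodulation.
#'
#' Defaults give a modulation index `m = 4 pi L0 dlambda / lambda^2`
#' near 2.6, where the first- and second-harmonic Bessel weights J1(m),
#' J2(m) are balanced.
#'
#' @param wavelength laser wavelength lambda (m), default 1550 nm
#'   (telecom single-mode fiber).
#' @param cavity_length rest fiber-cantilever gap L0 (m).
#' @param visibility fringe visibility V in (0, 1].
#' @param mean_intensity mean detector intensity I0 (arbitrary units).
#' @param modulation_depth wavelength modulation amplitude (m).
#' @param modulation_frequency wavelength modulation frequency (Hz); must
#'   be far above the mechanical signal band.
#' @return object of class `cavity_config`.
#' @export
cavity_config <- function(wavelength = 1.55e-6, cavity_length = 500e-6,
                          visibility = 0.8, mean_intensity = 1.0,
                          modulation_depth = 1e-9,
                          modulation_frequency = 500) {
  stopifnot(wavelength > 0, cavity_length > 0,
            visibility > 0, visibility <= 1,
            mean_intensity > 0, modulation_depth >= 0,
            modulation_frequency > 0)
  structure(list(wavelength = wavelength, cavity_length = cavity_length,
                 visibility = visibility, mean_intensity = mean_intensity,
                 modulation_depth = modulation_depth,
                 modulation_frequency = modulation_frequency),
            class = "cavity_config")
}

#' Interferometric fringe intensity for a cantilever deflection
#'
#' @param deflection cantilever deflection d (m); must satisfy `d < L0`
#'   (the cantilever must not crash into the fiber facet).
#' @param cavity a [cavity_config()].
#' @param t sample times (s) for the instantaneous modulated wavelength;
#'   default 0 (no modulation phase).
#' @return intensity in the same arbitrary units as `mean_intensity`.
#' @export
fringe_intensity <- function(deflection, cavity, t = 0) {
  stopifnot(inherits(cavity, "cavity_config"))
  if (any(deflection >= cavity$cavity_length))
    stop("fringe_intensity: deflection reaches the fiber facet (cavity collapse)",
         call. = FALSE)
  lam_t <- cavity$wavelength +
    cavity$modulation_depth * sin(2 * pi * cavity$modulation_frequency * t)
  cavity$mean_intensity *
    (1 + cavity$visibility *
       cos(4 * pi * (cavity$cavity_length - deflection) / lam_t))
}

# zero-phase lowpass spanning exactly one modulation period (nulls all
# modulation harmonics): for odd n a plain centered boxcar of length n,
# for even n a centered kernel of length n+1 with half weights at the
# ends (a plain even boxcar would carry a half-sample delay, which shows
# up as a spurious phase lag at the top of the sweep band). Edge samples
# without a full window, where the lock-in harmonics would leak, are
# held at the nearest fully-averaged value.
moving_average <- function(x, n) {
  N <- length(x)
  i <- seq_len(N)
  out <- numeric(N)
  cs <- cumsum(c(0, x))
  if (n %% 2L == 1L) {
    half <- (n - 1L) %/% 2L
    lo <- i - half
    hi <- i + half
    valid <- which(lo >= 1L & hi <= N)
    out[valid] <- (cs[hi[valid] + 1L] - cs[lo[valid]]) / n
  } else {
    half <- n %/% 2L
    lo <- i - half
    hi <- i + half
    valid <- which(lo >= 1L & hi <= N)
    out[valid] <- (cs[hi[valid] + 1L] - cs[lo[valid]] -
                     0.5 * (x[lo[valid]] + x[hi[valid]])) / n
  }
  if (length(valid)) {
    out[i < valid[1L]] <- out[valid[1L]]
    out[i > valid[length(valid)]] <- out[valid[length(valid)]]
  }
  out
}

#' Demodulate a wavelength-modulated fringe intensity to deflection
#'
#' Software lock-in on the wavelength-modulation harmonics. Writing the
#' cavity phase `theta = 4 pi (L0 - d)/lambda`, the modulated intensity
#' expands in Bessel harmonics of the modulation frequency `f_m`; the
#' lock-in components at `f_m` and `2 f_m` are proportional to
#' `-sin(theta) J1(m)` and `cos(theta) J2(m)`, from which `theta` is
#' recovered by `atan2` (ratiometric: insensitive to `I0` and `V`),
#' unwrapped across fringes, and converted to deflection
#' `d = -lambda theta / (4 pi)` up to an additive constant.
#'
#' A second pass refines the position-dependent modulation index
#' `m(d) = 4 pi (L0 - d) dlambda / lambda^2` from the first-pass estimate.
#'
#' @param intensity sampled intensity series.
#' @param cavity a [cavity_config()].
#' @param sample_rate sampling rate (Hz); must be at least 10x the
#'   modulation frequency.
#' @param visibility_threshold minimum estimated fringe visibility;
#'   below it the probe readout is considered unusable.
#' @param refine logical; apply the second-pass modulation-index
#'   refinement (default TRUE).
#' @return deflection series in m, zero-mean (the absolute offset is not
#'   observable interferometrically).
#' @export
demodulate_intensity <- function(intensity, cavity, sample_rate,
                                 visibility_threshold = 0.1, refine = TRUE) {
  stopifnot(inherits(cavity, "cavity_config"))
  fm <- cavity$modulation_frequency
  if (sample_rate < 10 * fm)
    stop("demodulate_intensity: sample_rate must be >= 10x the modulation frequency",
         call. = FALSE)
  nwin <- round(sample_rate / fm)
  if (abs(nwin - sample_rate / fm) > 1e-6)
    stop("demodulate_intensity: sample_rate must be an integer multiple of the modulation frequency",
         call. = FALSE)
  n <- length(intensity)
  t <- (seq_len(n) - 1) / sample_rate
  wm <- 2 * pi * fm
  X <- moving_average(intensity * (2 * sin(wm * t)), nwin)
  Y <- moving_average(intensity * (2 * cos(2 * wm * t)), nwin)
  m0 <- 4 * pi * cavity$cavity_length * cavity$modulation_depth /
    cavity$wavelength^2
  # cos(phi - m sin(wm t)) expands to J0(m) cos(phi)
  #   + 2 J1(m) sin(phi) sin(wm t) + 2 J2(m) cos(phi) cos(2 wm t) + ...
  # so X ~ 2 I0 V J1(m) sin(phi) and Y ~ 2 I0 V J2(m) cos(phi)
  extract_theta <- function(sx, sy) {
    theta <- atan2(X / sx, Y / sy)
    amp <- sqrt((X / sx)^2 + (Y / sy)^2)               # = 2 I0 V
    v_est <- 0.5 * mean(amp) / mean(intensity)
    if (v_est < visibility_threshold)
      stop("demodulate_intensity: fringe visibility below threshold (",
           signif(v_est, 3), " < ", visibility_threshold,
           "); probe readout unusable", call. = FALSE)
    dphi <- diff(theta)
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
    if (any(abs(dphi) > pi / 2))
      stop("demodulate_intensity: phase-unwrap jump too large between samples; ",
           "deflection slew exceeds the readout capture range", call. = FALSE)
    cumsum(c(theta[1], dphi))
  }
  theta <- extract_theta(2 * besselJ(m0, 1), 2 * besselJ(m0, 2))
  # when the deflection spans multiple fringes the quadrature scales can
  # be normalized from the data itself (ellipse normalization), which is
  # independent of the nominal modulation index; for sub-fringe signals
  # keep the Bessel weights of the configured index
  if (refine && (max(theta) - min(theta)) > 2 * pi) {
    theta <- extract_theta(stats::quantile(abs(X), 0.999, names = FALSE),
                           stats::quantile(abs(Y), 0.999, names = FALSE))
  }
  d <- -cavity$wavelength * theta / (4 * pi)
  d - mean(d)
}
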
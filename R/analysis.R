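#' Single-frequency sinusoid extraction (software lock-in)
#'
#' Least-squares fit of `a sin(2 pi f t) + b cos(2 pi f t) + c + e t` to a
#' uniformly sampled segment; the linear term absorbs slow drift. The
#' amplitude is `sqrt(a^2 + b^2)` and the phase is `atan2(b, a)`, i.e. the
#' signal is represented as `A sin(2 pi f t + phi)`. The same convention is
#' used for every channel, so phase DIFFERENCES between channels fitted
#' over the same time base are convention-free. On integer-period,
#' drift-free segments the estimate coincides with the single-bin discrete
#' Fourier projection.
#'
#' @param x signal samples.
#' @param frequency known oscillation frequency (Hz).
#' @param sample_rate sampling rate (Hz); ignored when `t` is given.
#' @param t optional explicit sample times (s).
#' @return list with `amplitude`, `phase` (rad), `offset`, `drift_slope`
#'   (per s), and `residual_rms`.
#' @export
extract_sinusoid <- function(x, frequency, sample_rate = NULL, t = NULL) {
  if (is.null(t)) {
    if (is.null(sample_rate))
      stop("extract_sinusoid: give either 'sample_rate' or 't'", call. = FALSE)
    t <- (seq_along(x) - 1) / sample_rate
  }
  if (length(x) != length(t))
    stop("extract_sinusoid: 'x' and 't' lengths differ", call. = FALSE)
  dur <- t[length(t)] - t[1L]
  if (dur < 2 / frequency)
    stop("extract_sinusoid: segment shorter than 2 periods at ", frequency,
         " Hz (insufficient data)", call. = FALSE)
  w <- 2 * pi * frequency
  tc <- t - mean(t)
  X <- cbind(sin(w * t), cos(w * t), 1, tc)
  fit <- stats::lm.fit(X, x)
  cf <- fit$coefficients
  list(amplitude = unname(sqrt(cf[1L]^2 + cf[2L]^2)),
       phase = unname(atan2(cf[2L], cf[1L])),
       offset = unname(cf[3L]),
       drift_slope = unname(cf[4L]),
       residual_rms = sqrt(mean(fit$residuals^2)))
}

#' Analysis settings for [analyze_sweep()]
#'
#' @param discard_periods oscillation periods dropped at the start of each
#'   segment before fitting (controller and sample-memory settling).
#' @param linearity_bound maximum `h1/h0` before the linearity flag.
#' @param geometry_bound maximum `h0/R` before the geometry flag.
#' @param max_static_depth maximum static indentation depth (m) before the
#'   depth flag.
#' @param residual_ratio_bound maximum fit-residual-to-amplitude ratio on
#'   either channel before the waveform is considered distorted and the
#'   phase unreliable (`phase_unreliable` flag); stick-slip friction at
#'   low sweep frequencies trips this.
#' @param phase_clip_tol small negative fitted phases (|phi| below this,
#'   rad) are clipped to 0 with a `negative_phase_clipped` flag instead of
#'   propagating a negative loss modulus.
#' @return list of settings.
#' @export
analysis_settings <- function(discard_periods = 1,
                              linearity_bound = 0.05,
                              geometry_bound = 0.4,
                              max_static_depth = 40e-6,
                              residual_ratio_bound = 0.05,
                              phase_clip_tol = 0.05) {
  list(discard_periods = discard_periods,
       linearity_bound = linearity_bound,
       geometry_bound = geometry_bound,
       max_static_depth = max_static_depth,
       residual_ratio_bound = residual_ratio_bound,
       phase_clip_tol = phase_clip_tol)
}

#' Analyze a recording into per-frequency storage and loss moduli
#'
#' For each oscillation segment: discard the first `discard_periods`
#' periods, truncate to a whole number of periods (so higher harmonics
#' stay orthogonal to the fundamental), compute the indentation
#' `h(t) = z_p(t) - d(t) - z_contact`, fit single-frequency sinusoids to
#' load and indentation, form the amplitudes `F1`, `h1` and the phase lag
#' `phi = phase(load) - phase(indentation)`, take the static depth `h0`
#' as the segment-mean indentation, and invert through
#' [moduli_from_oscillation()]. Quality-control flags (linearity,
#' geometry, maximum static depth, waveform distortion / low-frequency
#' phase reliability, clipped negative phase) are attached per row, never
#' dropped silently.
#'
#' @param recording a `recording` (deflection or raw-intensity fidelity;
#'   intensity channels are demodulated first using the cavity metadata).
#' @param contact a [contact_config()]; default from the recording
#'   metadata.
#' @param settings an [analysis_settings()] list.
#' @param z_contact contact piezo position (m); default: re-detected from
#'   the approach segment via [detect_contact()], falling back to the
#'   recording metadata.
#' @return object of class `sweep_result`: data frame rows sorted by
#'   frequency with columns `frequency`, `F1`, `h1`, `phase`, `h0`,
#'   `storage`, `loss`, `qc_flags`, plus metadata.
#' @export
analyze_sweep <- function(recording, contact = NULL,
                          settings = analysis_settings(),
                          z_contact = NULL) {
  stopifnot(inherits(recording, "recording"))
  dat <- recording$data
  meta <- recording$meta
  fs <- meta$protocol$sample_rate
  if (is.null(contact))
    contact <- contact_config(meta$contact$bead_radius,
                              meta$contact$poisson_ratio)
  if (identical(meta$signal, "intensity")) {
    cav <- do.call(cavity_config, meta$cavity)
    dat$deflection <- demodulate_intensity(dat$intensity, cav, fs)
    dat$load <- meta$probe$spring_constant * dat$deflection
  }
  if (is.null(z_contact)) {
    z_contact <- tryCatch(detect_contact(recording)$z_contact,
                          error = function(e) meta$z_contact)
    if (is.null(z_contact))
      stop("analyze_sweep: contact position unknown (no approach segment and no metadata)",
           call. = FALSE)
  }

  osc <- grep("^oscillation@", dat$segment_label, value = FALSE)
  if (!length(osc))
    stop("analyze_sweep: recording has no oscillation segments", call. = FALSE)

  # per-channel measurement noise floor from the (detrended) tail of the
  # static hold, so the waveform-distortion bound adapts to the
  # instrument's own noise rather than flagging clean low-amplitude sweeps
  # the first-difference MAD is insensitive to slow controller motion (and
  # to sparse slip events), so it isolates the broadband sample-to-sample
  # noise even when the hold itself carries a disturbance
  hold <- which(dat$segment_label == "hold")
  sig_F <- sig_h <- 0
  if (length(hold) > 100L) {
    tail_idx <- hold[max(1L, length(hold) - 10L * fs):length(hold)]
    diff_mad <- function(y) stats::mad(diff(y)) / sqrt(2)
    sig_F <- diff_mad(dat$load[tail_idx])
    sig_h <- diff_mad(dat$piezo_position[tail_idx] - dat$deflection[tail_idx])
  }

  labs <- unique(dat$segment_label[osc])
  rows <- lapply(labs, function(lb) {
    f <- as.numeric(sub("^oscillation@(.*)Hz$", "\\1", lb))
    idx <- which(dat$segment_label == lb)
    drop <- round(settings$discard_periods * fs / f)
    if (drop > 0) idx <- idx[-seq_len(min(drop, length(idx) - 1L))]
    nper <- floor(length(idx) * f / fs)
    if (nper < 2)
      stop("analyze_sweep: fewer than 2 clean periods at ", f, " Hz",
           call. = FALSE)
    idx <- idx[seq_len(round(nper * fs / f))]
    tt <- dat$time[idx] - dat$time[idx[1L]]
    h <- dat$piezo_position[idx] - dat$deflection[idx] - z_contact
    fitF <- extract_sinusoid(dat$load[idx], f, t = tt)
    fith <- extract_sinusoid(h, f, t = tt)
    phi <- fitF$phase - fith$phase
    phi <- atan2(sin(phi), cos(phi))
    h0 <- mean(h)
    flags <- character(0)
    if (phi < 0 && phi > -settings$phase_clip_tol) {
      phi <- 0
      flags <- c(flags, "negative_phase_clipped")
    }
    # waveform distortion beyond the broadband noise floor (quadrature
    # excess); harmonic content from e.g. stick-slip transmission friction
    # invalidates the single-frequency phase estimate
    excess_F <- sqrt(max(fitF$residual_rms^2 - sig_F^2, 0))
    excess_h <- sqrt(max(fith$residual_rms^2 - sig_h^2, 0))
    if (excess_F > max(settings$residual_ratio_bound * fitF$amplitude, sig_F) ||
        excess_h > max(settings$residual_ratio_bound * fith$amplitude, sig_h))
      flags <- c(flags, "phase_unreliable")
    if (h0 > settings$max_static_depth) flags <- c(flags, "max_depth")
    data.frame(frequency = f, F1 = fitF$amplitude, h1 = fith$amplitude,
               phase = phi, h0 = h0,
               pre_flags = paste(flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  obs <- do.call(rbind, rows)
  obs <- obs[order(obs$frequency), , drop = FALSE]
  mod <- moduli_from_oscillation(obs, contact,
                                 linearity_bound = settings$linearity_bound,
                                 geometry_bound = settings$geometry_bound)
  qc <- mapply(function(a, b) paste(setdiff(unique(c(
    strsplit(a, ",")[[1L]], strsplit(b, ",")[[1L]])), ""), collapse = ","),
    obs$pre_flags, mod$qc_flags, USE.NAMES = FALSE)
  out <- data.frame(frequency = obs$frequency, F1 = obs$F1, h1 = obs$h1,
                    phase = obs$phase, h0 = obs$h0,
                    storage = mod$storage, loss = mod$loss,
                    qc_flags = qc, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (all(nzchar(out$qc_flags)))
    warning("analyze_sweep: every frequency row carries a QC flag")
  structure(list(table = out,
                 meta = list(source_seed = meta$seed,
                             model = meta$model,
                             contact = unclass(contact),
                             z_contact = z_contact,
                             settings = settings)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result>", nrow(x$table), "frequencies\n")
  tb <- x$table
  tb$storage <- signif(tb$storage, 5)
  tb$loss <- signif(tb$loss, 5)
  print(tb[, c("frequency", "storage", "loss", "phase", "qc_flags")],
        row.names = FALSE)
  invisible(x)
}

#' Aggregate repeated frequency sweeps
#'
#' Per-frequency arithmetic mean and standard deviation of the storage
#' and loss moduli over repeated sweeps on the same location (no
#' weighting). Flagged rows are excluded by default; a single retained
#' value has dispersion 0 by convention.
#'
#' @param results list of `sweep_result` objects sharing one frequency
#'   grid.
#' @param exclude_flagged drop QC-flagged rows from the aggregation.
#' @return object of class `aggregate_result`: data frame with columns
#'   `frequency`, `storage_mean`, `storage_sd`, `loss_mean`, `loss_sd`,
#'   `n`.
#' @export
aggregate_sweeps <- function(results, exclude_flagged = TRUE) {
  if (inherits(results, "sweep_result")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, TRUE, "sweep_result")))
  grids <- lapply(results, function(r) r$table$frequency)
  for (g in grids[-1L])
    if (length(g) != length(grids[[1L]]) ||
        any(abs(g - grids[[1L]]) > 1e-9 * grids[[1L]]))
      stop("aggregate_sweeps: sweeps have incompatible frequency grids",
           call. = FALSE)
  f <- grids[[1L]]
  agg <- lapply(seq_along(f), function(i) {
    st <- vapply(results, function(r) r$table$storage[i], 0)
    lo <- vapply(results, function(r) r$table$loss[i], 0)
    keep <- if (exclude_flagged)
      !nzchar(vapply(results, function(r) r$table$qc_flags[i], "")) else
        rep(TRUE, length(results))
    st <- st[keep]; lo <- lo[keep]
    n <- length(st)
    data.frame(frequency = f[i],
               storage_mean = if (n) mean(st) else NA_real_,
               storage_sd = if (n > 1) stats::sd(st) else if (n) 0 else NA_real_,
               loss_mean = if (n) mean(lo) else NA_real_,
               loss_sd = if (n > 1) stats::sd(lo) else if (n) 0 else NA_real_,
               n = n)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  structure(list(table = out, n_sweeps = length(results)),
            class = "aggregate_result")
}

#' @export
print.aggregate_result <- function(x, ...) {
  cat("<aggregate_result> over", x$n_sweeps, "sweeps\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
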
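test_that("frequency grids match the protocol presets", {
  full <- frequency_grid(sweep_protocol("full_band"))
  expect_length(full, 15)
  expect_equal(full[1], 0.05)
  expect_equal(full[15], 10)
  expect_true(all(diff(full) > 0))
  expect_equal(diff(log10(full)), rep(diff(log10(c(0.05, 10))) / 14, 14))

  np <- frequency_grid(sweep_protocol("np_mode"))
  expect_length(np, 5)
  expect_equal(np[1], 0.5)
  expect_equal(np[5], 10)

  two <- frequency_grid(sweep_protocol(f_min = 0.2, f_max = 7,
                                       n_frequencies = 2))
  expect_equal(two, c(0.2, 7))
  expect_error(sweep_protocol(n_frequencies = 1), ">= 2")
})

test_that("segments partition the recording and cover the periods", {
  proto <- sweep_protocol("np_mode", hold_time = 5)
  rec <- simulate_measurement(truth_models()$pdms_sls$model,
                              protocol = proto, seed = 3)
  seg <- rle(rec$data$segment_label)
  expect_equal(sum(seg$lengths), nrow(rec$data))
  freqs <- frequency_grid(proto)
  osc_len <- seg$lengths[grepl("^oscillation@", seg$values)]
  expect_true(all(osc_len / proto$sample_rate >=
                    proto$periods_per_frequency / freqs - 1e-9))
})

test_that("same seed and configuration give a bit-identical recording", {
  mm <- truth_models()$pdms_sls
  proto <- sweep_protocol("np_mode", hold_time = 5)
  r1 <- simulate_measurement(mm$model, protocol = proto, seed = 42)
  r2 <- simulate_measurement(mm$model, protocol = proto, seed = 42)
  expect_identical(r1$data, r2$data)
  r3 <- simulate_measurement(mm$model, protocol = proto, seed = 43)
  expect_false(identical(r3$data$deflection, r1$data$deflection))
})

test_that("load control holds the static setpoint and tracks the sweep", {
  mm <- truth_models()$pdms_sls
  proto <- sweep_protocol("full_band", static_load = mm$static_load)
  rec <- simulate_measurement(mm$model, protocol = proto, seed = 4)
  dat <- rec$data
  fs <- proto$sample_rate
  hold <- which(dat$segment_label == "hold")
  settled <- hold[hold > hold[1] + 10 * fs]
  expect_lt(abs(mean(dat$load[settled]) - proto$static_load) /
              proto$static_load, 0.01)
  # commanded oscillation amplitude tracked within 2 % at every frequency
  for (lb in unique(grep("^oscillation@", dat$segment_label, value = TRUE))) {
    f <- as.numeric(sub("^oscillation@(.*)Hz$", "\\1", lb))
    idx <- which(dat$segment_label == lb)
    idx <- idx[-seq_len(round(fs / f))]          # first period settles
    fit <- extract_sinusoid(dat$load[idx], f, t = dat$time[idx])
    expect_lt(abs(fit$amplitude - proto$oscillation_amplitude) /
                proto$oscillation_amplitude, 0.02)
  }
})

test_that("indentation lags the load by a non-negative phase for passive samples", {
  models <- truth_models()[c("soft_sls", "kelvin_voigt")]
  for (mm in models) {
    proto <- sweep_protocol("np_mode", static_load = mm$static_load)
    rec <- simulate_measurement(mm$model, quiet_probe(), protocol = proto,
                                seed = 5)
    res <- analyze_sweep(rec)
    expect_true(all(res$table$phase >= -1e-6))
  }
  # purely elastic: phase indistinguishable from zero, loss below noise floor
  proto <- sweep_protocol("np_mode", static_load = 150e-6)
  rec <- simulate_measurement(rheology_model("elastic", G_e = 10e3),
                              quiet_probe(), protocol = proto, seed = 6)
  res <- analyze_sweep(rec)
  expect_true(all(abs(res$table$phase) < 1e-4))
  expect_true(all(res$table$loss < 1))
})

test_that("indentation stays non-negative within noise during contact", {
  mm <- truth_models()$pdms_sls
  proto <- sweep_protocol("np_mode", hold_time = 5)
  rec <- simulate_measurement(mm$model, protocol = proto, seed = 7)
  dat <- rec$data
  zs <- rec$meta$z_surface_true
  contact_seg <- dat$segment_label %in%
    c("hold", grep("^oscillation@", dat$segment_label, value = TRUE))
  h <- dat$piezo_position[contact_seg] - dat$deflection[contact_seg] - zs
  expect_true(all(h >= -3 * rec$meta$probe$deflection_noise_rms))
})

test_that("contact detection finds the surface and rejects spurious spikes", {
  mm <- truth_models()$pdms_sls
  proto <- sweep_protocol("np_mode", hold_time = 5)
  rec <- simulate_measurement(mm$model, quiet_probe(), protocol = proto,
                              seed = 8)
  dc <- detect_contact(rec)
  expect_lt(abs(dc$z_contact - rec$meta$z_surface_true), 1e-7)

  # synthetic approach with a one-sample spurious spike before true contact
  fs <- 1000
  n <- 3000
  load <- rep(0, n)
  load[1000] <- 5e-6                      # contamination spike
  load[2001:n] <- seq(0, 3e-4, length.out = 1000)
  fake <- structure(list(
    data = data.frame(time = (seq_len(n) - 1) / fs,
                      piezo_position = (seq_len(n) - 1) * 1e-8,
                      deflection = load / 65, load = load,
                      segment_label = "approach",
                      stringsAsFactors = FALSE),
    meta = list(probe = list(spring_constant = 65,
                             deflection_noise_rms = 0),
                protocol = list(sample_rate = fs))), class = "recording")
  dc <- detect_contact(fake, threshold = 1e-6)
  expect_gte(dc$index, 2001)

  # all-noise recording below threshold: no contact
  fake$data$load <- rep(1e-8, n)
  fake$data$deflection <- fake$data$load / 65
  expect_error(detect_contact(fake, threshold = 1e-6), "no contact")
})

test_that("glass calibration recovers sensitivity scale and offset", {
  proto <- sweep_protocol("np_mode", hold_time = 5)
  rec <- simulate_measurement(NULL, probe_config(), protocol = proto,
                              seed = 9, rigid = TRUE)
  cal <- calibrate_on_glass(rec)
  expect_equal(cal$scale, 1, tolerance = 1e-3)
  expect_lt(abs(cal$offset - proto$approach_gap), 5e-7)
  expect_true(cal$ok)

  # injected 3 % sensitivity miscalibration is recovered
  rec3 <- simulate_measurement(NULL, probe_config(sensitivity_scale = 1.03),
                               protocol = proto, seed = 10, rigid = TRUE)
  cal3 <- calibrate_on_glass(rec3)
  expect_equal(cal3$scale, 1.03, tolerance = 0.005)

  # a badly miscalibrated probe raises the rejection signal
  rec7 <- simulate_measurement(NULL, probe_config(sensitivity_scale = 0.7),
                               protocol = proto, seed = 11, rigid = TRUE)
  expect_warning(cal7 <- calibrate_on_glass(rec7), "discarded")
  expect_false(cal7$ok)

  # on glass the piezo motion converts one-to-one into deflection (h ~ 0)
  dat <- rec$data
  sel <- which(dat$segment_label == "approach" &
                 dat$load > 0.1 * proto$static_load &
                 dat$load < 0.9 * proto$static_load)
  slope <- diff(range(dat$deflection[sel])) /
    diff(range(dat$piezo_position[sel]))
  expect_equal(slope, 1, tolerance = 0.01)
})

test_that("an unreachable load setpoint raises a protocol fault", {
  soft <- rheology_model("elastic", G_e = 200)   # 200 Pa: needs > 500 um
  expect_error(
    simulate_measurement(soft, quiet_probe(),
                         protocol = sweep_protocol("np_mode", hold_time = 2,
                                                   static_load = 3e-4),
                         seed = 12),
    "piezo travel|no contact")
})

test_that("springpot samples cannot be simulated in the time domain", {
  expect_error(
    simulate_measurement(rheology_model("springpot", c_alpha = 100,
                                        alpha = 0.5), seed = 1),
    "frequency-domain")
})
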
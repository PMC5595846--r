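test_that("sinusoid extraction is exact on clean signals", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  x <- 1.0 * sin(2 * pi * 1.3 * t + 0.77) + 2.5
  fit <- extract_sinusoid(x, 1.3, fs)
  expect_equal(fit$amplitude, 1, tolerance = 1e-10)
  expect_equal((fit$phase - 0.77 + pi) %% (2 * pi) - pi, 0, tolerance = 1e-10)
  expect_error(extract_sinusoid(x[1:100], 1.3, fs), "insufficient|2 periods")
})

test_that("linear drift of 10 % per segment barely perturbs the amplitude", {
  fs <- 1000
  t <- seq(0, 5, by = 1 / fs)
  x <- sin(2 * pi * 1 * t) + 0.1 * t / 5
  fit <- extract_sinusoid(x, 1, fs)
  expect_lt(abs(fit$amplitude - 1), 0.005)
  expect_equal(fit$drift_slope, 0.1 / 5, tolerance = 0.01)
})

test_that("noisy extraction matches the DFT-bin oracle within mutual error", {
  fs <- 1000
  f <- 2
  t <- seq(0, 5 / f, by = 1 / fs)[- (5 * fs / f + 1)]  # 5 integer periods
  set.seed(21)
  noise_sd <- 10^(-30 / 20)                             # 30 dB SNR
  x <- sin(2 * pi * f * t + 0.4) + rnorm(length(t), sd = noise_sd)
  fit <- extract_sinusoid(x, f, fs)
  expect_lt(abs(fit$amplitude - 1), 0.02)
  expect_lt(abs(((fit$phase - 0.4 + pi) %% (2 * pi)) - pi), 1 * pi / 180)
  ora <- dft_single_bin(x, f, fs)
  expect_lt(abs(fit$amplitude - ora$amplitude), 0.01)
  expect_lt(abs(fit$phase - ora$phase), 0.01)
})

test_that("least squares equals the Fourier projection on integer periods", {
  fs <- 500
  f <- 5
  n <- fs / f * 4                                       # 4 integer periods
  t <- (seq_len(n) - 1) / fs
  x <- 0.8 * sin(2 * pi * f * t + 1.1) + 3
  fit <- extract_sinusoid(x, f, t = t)
  ora <- dft_single_bin(x, f, fs)
  expect_lt(abs(fit$amplitude - ora$amplitude) / ora$amplitude, 1e-10)
  expect_lt(abs(fit$phase - ora$phase), 1e-10)
})

test_that("a common time shift leaves the phase difference unchanged", {
  fs <- 1000
  t <- seq(0, 4, by = 1 / fs)
  load <- sin(2 * pi * 1.7 * t + 0.9)
  ind <- sin(2 * pi * 1.7 * t + 0.55)
  d0 <- extract_sinusoid(load, 1.7, t = t)$phase -
    extract_sinusoid(ind, 1.7, t = t)$phase
  d1 <- extract_sinusoid(load, 1.7, t = t + 123.456)$phase -
    extract_sinusoid(ind, 1.7, t = t + 123.456)$phase
  expect_equal(d0, d1, tolerance = 1e-9)
  expect_equal(d0, 0.35, tolerance = 1e-9)
})

test_that("noise-free sweep analysis recovers the model within 2 %", {
  mm <- truth_models()$soft_sls
  proto <- sweep_protocol("np_mode", static_load = mm$static_load)
  rec <- simulate_measurement(mm$model, quiet_probe(), protocol = proto,
                              seed = 31)
  res <- analyze_sweep(rec)
  truth <- complex_modulus(mm$model, res$table$frequency)
  expect_true(all(res$table$qc_flags == ""))
  expect_true(all(abs(res$table$storage - truth$storage) /
                    truth$storage < 0.02))
  expect_true(all(abs(res$table$loss - truth$loss) / truth$loss < 0.02))
  expect_true(all(diff(res$table$frequency) > 0))
})

test_that("full-band and reduced sweeps agree at shared frequencies", {
  mm <- truth_models()$pdms_sls
  rec_np <- simulate_measurement(mm$model, quiet_probe(),
                                 protocol = sweep_protocol("np_mode"),
                                 seed = 32)
  rec_fb <- simulate_measurement(mm$model, quiet_probe(),
                                 protocol = sweep_protocol("full_band"),
                                 seed = 33)
  res_np <- analyze_sweep(rec_np)
  res_fb <- analyze_sweep(rec_fb)
  shared <- c(0.5, 10)       # band edges present in both grids
  for (f in shared) {
    i <- which.min(abs(res_np$table$frequency - f))
    j <- which.min(abs(res_fb$table$frequency - f))
    expect_equal(res_np$table$storage[i], res_fb$table$storage[j],
                 tolerance = 0.02)
    expect_equal(res_np$table$loss[i], res_fb$table$loss[j],
                 tolerance = 0.05)
  }
})

test_that("aggregation averages sweeps and respects QC flags", {
  mm <- truth_models()$pdms_sls
  proto <- sweep_protocol("np_mode", static_load = mm$static_load)
  res <- analyze_sweep(simulate_measurement(mm$model, protocol = proto,
                                            seed = 34))
  # identical sweeps: zero dispersion
  agg <- aggregate_sweeps(list(res, res, res, res, res))
  expect_equal(agg$table$storage_sd, rep(0, 5))
  expect_equal(agg$table$storage_mean, res$table$storage)
  expect_equal(agg$table$n, rep(5L, 5))
  # single sweep: mean equals input, dispersion 0 by convention
  agg1 <- aggregate_sweeps(list(res))
  expect_equal(agg1$table$storage_mean, res$table$storage)
  expect_equal(agg1$table$loss_sd, rep(0, 5))
  # flagged rows are excluded
  res_fl <- res
  res_fl$table$qc_flags[2] <- "phase_unreliable"
  agg2 <- aggregate_sweeps(list(res, res_fl))
  expect_equal(agg2$table$n, c(2L, 1L, 2L, 2L, 2L))
  # incompatible grids are rejected
  res_bad <- res
  res_bad$table$frequency[1] <- 0.7
  expect_error(aggregate_sweeps(list(res, res_bad)), "incompatible")
})

test_that("repeated noisy sweeps average close to the ground truth", {
  mm <- truth_models()$pdms_sls
  proto <- sweep_protocol("np_mode", static_load = mm$static_load)
  res <- lapply(1:5, function(s)
    analyze_sweep(simulate_measurement(mm$model, protocol = proto, seed = s)))
  agg <- aggregate_sweeps(res)
  truth <- complex_modulus(mm$model, agg$table$frequency)
  expect_true(all(abs(agg$table$storage_mean - truth$storage) /
                    truth$storage < 0.05))
  expect_true(all(abs(agg$table$loss_mean - truth$loss) / truth$loss < 0.10))
})
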
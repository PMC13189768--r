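test_that("power_spectrum lands analytic peaks and scales consistently", {
  fps <- 30; n <- 160
  t <- 0:(n - 1)
  s <- sin(2 * pi * 1.5 * t / fps)
  ps <- power_spectrum(s, fps, n_fft = n)
  expect_equal(ps$freqs[which.max(ps$power)], 1.5)   # bin 8 at 0.1875 Hz
  expect_equal(which.max(ps$power) - 1L, 8L)
  expect_true(all(diff(ps$freqs) > 0))
  expect_true(all(ps$power >= 0))
  # Parseval: sum(power) * df recovers the mean square
  df <- fps / n
  expect_equal(sum(ps$power) * df, mean(s^2), tolerance = 1e-9)

  expect_equal(max(power_spectrum(rep(0, 64), fps)$power), 0)
})

test_that("white-noise periodogram is flat under averaging", {
  set.seed(10)
  fps <- 30; n <- 128
  acc <- 0
  reps <- 400
  for (i in 1:reps) acc <- acc + power_spectrum(rnorm(n), fps, n)$power
  avg <- acc / reps
  inner <- avg[2:(length(avg) - 1)]
  # density of unit white noise is 2/fs one-sided
  expect_equal(mean(inner), 2 / fps, tolerance = 0.02)
  expect_lt(sd(inner) / mean(inner), 0.15)
})

test_that("estimate_hr reads the banded periodogram peak", {
  fps <- 30; n <- 160
  t <- 0:(n - 1)
  expect_equal(estimate_hr(sin(2 * pi * 1.5 * t / fps), fps, n_fft = n), 90)

  # off-grid tone: matches a brute-force banded periodogram argmax
  w <- sin(2 * pi * 1.0 * t / fps)
  got <- estimate_hr(w, fps, n_fft = 160L)
  dtw <- pulseforge:::detrend_linear(w) * pulseforge:::hann_window(length(w))
  ps <- power_spectrum(dtw, fps, 160L)
  sel <- ps$freqs >= 0.6 & ps$freqs <= 3.3
  expect_equal(got, 60 * ps$freqs[sel][which.max(ps$power[sel])])
  expect_lt(abs(got - 60), 60 * fps / 160 + 1e-9)  # within one bin

  # strong sub-band drift is excluded by banding
  drift <- 5 * sin(2 * pi * 0.2 * t / fps) + 0.4 * sin(2 * pi * 1.2 * t / fps)
  expect_equal(estimate_hr(drift, fps), 72, tolerance = 2)

  expect_error(estimate_hr(rep(0, 100), fps), "degenerate")
  expect_error(estimate_hr(w, fps, band = c(20, 40)), "fps/2")
})

test_that("snr_db follows the fundamental-plus-harmonic convention", {
  fps <- 30
  t <- 0:899
  tone <- sin(2 * pi * 1.2 * t / fps)
  expect_gt(snr_db(tone, 72, fps), 20)

  # scale invariance
  expect_equal(snr_db(tone * 50, 72, fps), snr_db(tone, 72, fps),
               tolerance = 1e-9)

  # band-limited noise with no tone: negative in expectation
  set.seed(2)
  vals <- replicate(40, snr_db(bandpass(rnorm(900), fps), 72, fps))
  expect_lt(mean(vals), 0)

  # monotone in tone amplitude at fixed noise
  set.seed(3)
  noise <- rnorm(900, sd = 1)
  snrs <- vapply(c(2, 1, 0.5, 0.25, 0.125),
                 function(a) snr_db(a * tone + noise, 72, fps), numeric(1))
  expect_true(all(diff(snrs) < 0))

  expect_error(snr_db(tone, 20, fps), "band")
})

test_that("hr_metrics agrees with closed forms and a streaming oracle", {
  r <- hr_metrics(c(60, 72, 90), c(60, 72, 90))
  expect_equal(r$mae, 0); expect_equal(r$rmse, 0); expect_equal(r$mape, 0)
  expect_equal(r$rho, 1); expect_equal(r$bland_altman$bias, 0)

  r2 <- hr_metrics(c(72, 60), c(60, 72))
  expect_equal(r2$mae, 12)
  expect_equal(r2$rmse, 12)
  expect_equal(r2$mape, (20 + 100 * 12 / 72) / 2, tolerance = 1e-12)
  expect_equal(r2$rho, -1)

  set.seed(77)
  pred <- runif(10000, 40, 180); ref <- runif(10000, 40, 180)
  m <- hr_metrics(pred, ref)
  d <- pred - ref
  expect_equal(m$mae, sum(abs(d)) / 10000, tolerance = 1e-10)
  expect_equal(m$rmse, sqrt(sum(d^2) / 10000), tolerance = 1e-10)
  expect_equal(m$mape, 100 * sum(abs(d) / ref) / 10000, tolerance = 1e-10)
  expect_equal(m$rho, cor(pred, ref), tolerance = 1e-12)
  expect_equal(m$bland_altman$loa_high - m$bland_altman$loa_low,
               2 * 1.96 * sd(d), tolerance = 1e-10)
  expect_true(m$bland_altman$loa_low <= m$bland_altman$bias &&
                m$bland_altman$bias <= m$bland_altman$loa_high)

  expect_error(hr_metrics(1:3, 1:4), "length")
  expect_true(is.na(hr_metrics(c(60, 70), c(72, 72))$rho))
})

test_that("rmse is never below mae (power-mean inequality)", {
  set.seed(5)
  for (i in 1:200) {
    n <- sample(1:30, 1)
    m <- hr_metrics(runif(n, 40, 180), runif(n, 40, 180))
    expect_gte(m$rmse, m$mae - 1e-12)
    expect_gte(m$mape, 0)
  }
})

test_that("bandpass is zero-phase and band-selective", {
  fps <- 30
  t <- 0:599
  tone <- sin(2 * pi * 1.5 * t / fps)
  out <- bandpass(tone, fps)
  mid <- 150:450
  expect_equal(sd(out[mid]) / sd(tone[mid]), 1, tolerance = 0.05)
  # zero-phase: the in-band tone is not shifted
  expect_gt(cor(out[mid], tone[mid]), 0.99)

  dc <- bandpass(rep(5, 300), fps)
  expect_lt(max(abs(dc)), 1e-9)  # pure DC lies entirely outside the passband

  mix <- 3 * sin(2 * pi * 0.05 * t / fps) + sin(2 * pi * 1.2 * t / fps)
  ps <- power_spectrum(bandpass(mix, fps), fps, 1024L)
  expect_equal(ps$freqs[which.max(ps$power)], 1.2, tolerance = 0.05)

  expect_error(bandpass(tone, fps, band = c(3, 16)), "fps/2")
})

test_that("green_baseline reads the green-channel pulse", {
  cf <- synth_config(hr_bpm = 72, fps = 30, d = 300L, h = 32L, w = 32L,
                     noise_sd = 0, illum_amp = 0, jitter_px = 0L,
                     amp_mod_sd = 0, seed = 5L)
  s <- synth_clip(cf)
  wave <- green_baseline(s$clip)
  expect_length(wave, 300)
  expect_equal(estimate_hr(wave, 30), 72, tolerance = 30 * 60 / 512)

  # static clip -> essentially nothing after band-pass
  static <- frame_clip(array(0.5, dim = c(120, 3, 8, 8)), fps = 30)
  expect_lt(max(abs(green_baseline(static))), 1e-9)

  # linearity: doubling the modulation amplitude doubles the wave
  cf2 <- cf; cf2$pulse_amp <- cf$pulse_amp * 2
  s2 <- synth_clip(cf2)
  w1 <- green_baseline(s$clip); w2 <- green_baseline(s2$clip)
  mid <- 60:240
  expect_equal(sd(w2[mid]) / sd(w1[mid]), 2, tolerance = 0.02)

  mono <- frame_clip(array(0.5, dim = c(10, 1, 4, 4)), fps = 30)
  expect_error(green_baseline(mono), "3 channels")
})
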
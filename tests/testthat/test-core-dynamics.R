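test_that("windowed periodogram localizes tones and conserves power", {
  fs <- 1e3; n <- 1024
  t <- (0:(n - 1)) / fs
  w <- waveform(t, 3 * cos(2 * pi * 100 * t), unit = "V")
  ps <- power_spectrum(w)
  expect_lt(abs(ps$frequency[which.max(ps$psd)] - 100), ps$df)
  expect_lt(abs(ps$parseval_ratio - 1), 0.01)
  # two tones: both peaks present, no intermodulation above -100 dB
  w2 <- waveform(t, cos(2 * pi * 100 * t) + cos(2 * pi * 140 * t), unit = "V")
  p2 <- power_spectrum(w2)
  peak_power <- max(p2$psd)
  in_band <- function(f0) abs(p2$frequency - f0) < 4 * p2$df
  expect_gt(max(p2$psd[in_band(100)]), peak_power / 4)
  expect_gt(max(p2$psd[in_band(140)]), peak_power / 4)
  expect_lt(max(p2$psd[in_band(40)]), peak_power * 1e-10)
  expect_error(power_spectrum(waveform(c(0, 1, 3, 7) * 1e-3, rep(1, 4))),
               "uniform")
})

test_that("white noise yields an approximately flat spectrum", {
  set.seed(42)
  fs <- 1e3; n <- 8192
  w <- waveform((0:(n - 1)) / fs, rnorm(n), unit = "V")
  ps <- power_spectrum(w)
  f <- ps$frequency
  lo <- mean(ps$psd[f > 0.05 * fs / 2 & f < 0.45 * fs / 2])
  hi <- mean(ps$psd[f > 0.55 * fs / 2 & f < 0.95 * fs / 2])
  expect_lt(abs(lo / hi - 1), 0.15)
  # total power ~ variance (one-sided integral)
  expect_lt(abs(sum(ps$psd) * ps$df / var(w$values) - 1), 0.1)
})

test_that("zero AC drive transduces to the constant bias-point strain", {
  s <- drive_spec(amplitude_override = 0)
  out <- transduce(synthesize_drive(s), metglas)
  lam <- out$strain$values
  st <- self_consistent_state(c(0, 0, s$bias_B / mu0), mat = metglas)
  expect_equal(max(lam) - min(lam), 0, tolerance = 1e-12)
  expect_rel_equal(mean(lam), st$strain_me[3], 1e-6)
})

test_that("difference-frequency strain follows the a1*a2 intermodulation law", {
  # independent oracle: expanding lambda(B0 + d)^2 to second order makes the
  # cross term c2 * a1 * a2 * cos(2 pi (f2 - f1) t), so the log-log slope of
  # the demodulated amplitude in each tone amplitude is 1
  base <- 5.56e-5
  amps <- base * 10^seq(-1, 0, length.out = 5)
  slope_in <- function(which_tone) {
    dfamp <- vapply(amps, function(a) {
      a1 <- if (which_tone == 1) a else base
      a2 <- if (which_tone == 2) a else base
      tr <- transduce(two_tone_drive(a1, a2), metglas)
      tone_amplitude(tr$strain, 62e6)$amplitude
    }, numeric(1))
    unname(coef(lm(log(dfamp) ~ log(amps)))[2])
  }
  expect_lt(abs(slope_in(1) - 1), 0.05)
  expect_lt(abs(slope_in(2) - 1), 0.05)
})

test_that("quadratic mixing products appear in the core but not in the air control", {
  s <- drive_spec()
  rep <- demodulation_report(s, metglas)
  core <- rep$core_spectrum
  air <- rep$air_spectrum
  floor_core <- median(core$psd[core$frequency > 1e6])
  for (f0 in c(2 * s$f1, 2 * s$f2, s$f1 + s$f2)) {
    sel <- abs(core$frequency - f0) <= 3 * core$df
    expect_gt(max(core$psd[sel]), 100 * floor_core)   # present in the core
    sel_a <- abs(air$frequency - f0) <= 3 * air$df
    near_air <- median(air$psd[abs(air$frequency - f0) < 0.05 * f0])
    expect_lt(max(air$psd[sel_a]), 100 * near_air)    # absent in air
  }
})

test_that("difference-peak detection recovers an injected bin exactly", {
  f <- seq(0, 500e6, by = 1e6)
  psd <- rep(1e-12, length(f))
  psd[f == 62e6] <- 1e-6
  s <- structure(list(frequency = f, psd = psd, df = 1e6,
                      parseval_ratio = 1, window = "hann", fs = 1e9,
                      unit = "", label = "synthetic"),
                 class = "spectrum_psd")
  pk <- detect_difference_peak(s, 126e6, 188e6)
  expect_true(pk$found)
  expect_equal(pk$frequency, 62e6)
  expect_equal(pk$power, 1e-6)
  expect_rel_equal(pk$prominence_db, 60, 1e-6)
  expect_error(detect_difference_peak(s, 1e6, 900e6), "outside")
})

test_that("demodulation contrast: present in the core, absent in air, symmetric", {
  rep <- demodulation_report()
  expect_true(rep$core_peak$found)
  expect_false(rep$air_peak$found)
  expect_true(rep$contrast)
  expect_lt(abs(rep$core_peak$frequency - 62e6), 2 * rep$core_spectrum$df)
  # swapped tones give the identical difference frequency
  rep_swap <- demodulation_report(drive_spec(f1 = 188e6, f2 = 126e6))
  expect_equal(rep_swap$core_peak$frequency, rep$core_peak$frequency)
  # single-tone drive: no difference peak
  drive1 <- synthesize_drive(drive_spec())
  one_tone <- waveform(drive1$time,
                       0.293 + 5.5e-5 * cos(2 * pi * 126e6 * drive1$time),
                       unit = "T")
  ps1 <- power_spectrum(transduce(one_tone, metglas)$strain)
  pk1 <- detect_difference_peak(ps1, 126e6, 188e6)
  expect_false(pk1$found)
})

test_that("a resonator tuned to the beat amplifies it by about Q", {
  spec <- drive_spec(duration = 100 / 62e6)
  drive <- synthesize_drive(spec)
  off <- transduce(drive, metglas)
  on <- transduce(drive, metglas,
                  resonator_spec(62e6, quality_factor = 10, enabled = TRUE))
  a_off <- tone_amplitude(waveform_tail(off$strain), 62e6)$amplitude
  a_on <- tone_amplitude(waveform_tail(on$strain), 62e6)$amplitude
  expect_lt(abs(a_on / a_off - 10) / 10, 0.2)
})

test_that("spectra export the documented CSV columns", {
  w <- waveform(seq(0, 1, length.out = 256), rnorm(256), unit = "V")
  ps <- power_spectrum(w)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectrum_csv(ps, path)
  back <- read.csv(path)
  expect_named(back, c("frequency_Hz", "psd"))
})
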
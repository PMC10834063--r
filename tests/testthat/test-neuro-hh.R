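test_that("the resting state is a fixed point and stays quiet unstimulated", {
  rest <- hh_rest()
  p <- hh_params()
  # |dv/dt| at the relaxed state with i = 0
  dv <- (-p$gbar_K * rest$n^4 * (rest$v - p$VK) -
           p$gbar_Na * rest$m^3 * rest$h * (rest$v - p$VNa) -
           p$gL * (rest$v - p$VL)) / p$Cm
  expect_lt(abs(dv), 1e-6)
  tr <- hh_simulate(NULL, duration_ms = 500, store_every = 10L)
  expect_equal(detect_spikes(tr)$count, 0)
  expect_lt(max(abs(tr$v_m - rest$v)), 1)
  expect_true(all(tr$n >= 0 & tr$n <= 1))
  expect_true(all(tr$m >= 0 & tr$m <= 1))
  expect_true(all(tr$h >= 0 & tr$h <= 1))
})

test_that("sustained suprathreshold current drives repetitive firing", {
  dc <- waveform(c(0, 0.2), c(15, 15), unit = "uA/cm2")
  tr <- hh_simulate(dc, duration_ms = 200, store_every = 2L)
  sp <- detect_spikes(tr)
  expect_gte(sp$count, 5)
  # spike excursions bracket the repolarization/depolarization band
  expect_lt(min(tr$v_m), -70)
  expect_gt(max(tr$v_m), 30)
  expect_lt(max(tr$v_m), 60)
  # counts are invariant to the detection threshold across the spike body
  counts <- vapply(seq(-20, 10, by = 5), function(th)
    detect_spikes(tr, threshold = th)$count, numeric(1))
  expect_equal(length(unique(counts)), 1L)
})

test_that("integration agrees with an independent adaptive ODE solution", {
  skip_if_not_installed("deSolve")
  p <- hh_params()
  rates <- function(t, y, parms) {
    v <- y[1]; n <- y[2]; m <- y[3]; h <- y[4]
    an <- 0.01 * (v + 55) / (1 - exp(-(v + 55) / 10))
    bn <- 0.125 * exp(-(v + 65) / 80)
    am <- 0.1 * (v + 40) / (1 - exp(-(v + 40) / 10))
    bm <- 4 * exp(-(v + 65) / 18)
    ah <- 0.07 * exp(-(v + 65) / 20)
    bh <- 1 / (1 + exp(-(v + 35) / 10))
    I <- 10
    dv <- (I - p$gbar_K * n^4 * (v - p$VK) - p$gbar_Na * m^3 * h * (v - p$VNa) -
             p$gL * (v - p$VL)) / p$Cm
    list(c(dv, an * (1 - n) - bn * n, am * (1 - m) - bm * m,
           ah * (1 - h) - bh * h))
  }
  v0 <- -65
  an <- 0.01 * (v0 + 55) / (1 - exp(-(v0 + 55) / 10))
  bn <- 0.125 * exp(-(v0 + 65) / 80)
  am <- 0.1 * (v0 + 40) / (1 - exp(-(v0 + 40) / 10))
  bm <- 4 * exp(-(v0 + 65) / 18)
  ah <- 0.07 * exp(-(v0 + 65) / 20)
  bh <- 1 / (1 + exp(-(v0 + 35) / 10))
  y0 <- c(v0, an / (an + bn), am / (am + bm), ah / (ah + bh))
  times <- seq(0, 50, by = 0.01)
  ref <- deSolve::ode(y0, times, rates, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-10)
  dc <- waveform(c(0, 0.1), c(10, 10), unit = "uA/cm2")
  tr <- hh_simulate(dc, duration_ms = 50, dt_ms = 0.001)
  v_mine <- tr$v_m[seq(1, length(tr$v_m), by = 10)]   # every 0.01 ms
  expect_lt(max(abs(v_mine - ref[, 2])), 0.5)
})

test_that("halving the step changes no spike count and shifts times < 0.1 ms", {
  dc <- waveform(c(0, 0.15), c(12, 12), unit = "uA/cm2")
  tr1 <- hh_simulate(dc, duration_ms = 150, dt_ms = 0.01)
  tr2 <- hh_simulate(dc, duration_ms = 150, dt_ms = 0.005)
  s1 <- detect_spikes(tr1); s2 <- detect_spikes(tr2)
  expect_equal(s1$count, s2$count)
  expect_lt(max(abs(s1$spike_times - s2$spike_times)), 0.1)
})

test_that("spike detection applies threshold and refractory period", {
  flat <- structure(list(time_ms = seq(0, 100, by = 0.1),
                         v_m = rep(-65, 1001), dt_ms = 0.1),
                    class = "hh_trace")
  expect_equal(detect_spikes(flat)$count, 0)
  # synthetic triangle wave crossing 0 mV three times, spacing > refractory
  t <- seq(0, 30, by = 0.01)
  v <- 40 * (abs((t %% 10) - 5) < 2) - 20
  tri <- structure(list(time_ms = t, v_m = v, dt_ms = 0.01),
                   class = "hh_trace")
  expect_equal(detect_spikes(tri)$count, 3)
  # refractory longer than the spacing collapses the count
  expect_equal(detect_spikes(tri, refractory_ms = 25)$count, 1)
})

test_that("the low-pass filter passes the beat and rejects the carriers", {
  fs <- 3.008e9
  t <- (0:9999) / fs
  dc <- waveform(t, rep(2.5, 10000), unit = "V")
  expect_lt(max(abs(lowpass(dc, 100e6)$values - 2.5)), 2.5e-3)
  tone <- function(f) waveform(t, cos(2 * pi * f * t), unit = "V")
  gain <- function(f) {
    w <- lowpass(tone(f), 100e6)
    tone_amplitude(waveform_tail(w, 0.6), f)$amplitude
  }
  expect_gt(gain(62e6), 0.7)
  expect_lt(gain(188e6), 0.1)
  # two-pass attenuation one octave above cutoff exceeds 40 dB
  expect_lt(gain(200e6), 10^(-40 / 20))
  expect_error(lowpass(dc, 2e9), "Nyquist")
})

test_that("time rescaling dilates frequencies without touching values", {
  fs <- 3.008e9
  t <- (0:4999) / fs
  w <- waveform(t, cos(2 * pi * 62e6 * t), unit = "V")
  slow <- time_rescale(w, 1e6)
  expect_identical(slow$values, w$values)
  expect_rel_equal(tone_amplitude(slow, 62)$amplitude, 1, 1e-2)
  back <- time_rescale(slow, 1e-6)
  expect_equal(back$time, w$time)
  expect_identical(time_rescale(w, 1)$time, w$time)
})

test_that("interface current applies Ohm's law and area normalization", {
  t <- seq(0, 1e-3, length.out = 11)
  v <- waveform(t, rep(0.3, 11), unit = "V")
  spec <- stimulus_spec(interface_resistance = 1e6, effective_area = 1)
  i <- interface_current(v, spec)
  expect_equal(i$values, rep(0.3, 11))   # 0.3 uA over 1 cm^2
  spec2 <- stimulus_spec(interface_resistance = 0.5e6, effective_area = 1)
  expect_equal(interface_current(v, spec2)$values, rep(0.6, 11))
  expect_equal(interface_current(waveform(t, rep(0, 11), unit = "V"),
                                 spec)$values, rep(0, 11))
})

test_that("the demodulated stimulus entrains the membrane 1:1 at 62 Hz", {
  i_base <- stimulation_current()
  expect_equal(i_base$unit, "uA/cm2")
  # dominant spectral component of the stimulus sits in the stimulation band
  expect_gt(tone_amplitude(i_base, 62)$amplitude +
              tone_amplitude(i_base, 126)$amplitude,
            10 * tone_amplitude(i_base, 380)$amplitude)
  sc <- max(abs(i_base$values)) / 15
  w15 <- waveform(i_base$time, i_base$values / sc, unit = "uA/cm2")
  sp <- detect_spikes(hh_simulate(w15, duration_ms = 1000, store_every = 5L))
  expect_lte(abs(sp$count - 62), 2)
  expect_true(sp$regular)
})

test_that("the amplitude sweep exposes a threshold and a regular plateau", {
  i_base <- stimulation_current()
  sweep <- amplitude_sweep(i_base, peaks = c(0.5, 1, 2, 4, 8, 12, 16, 20),
                           duration_ms = 600)
  expect_named(sweep, c("scale", "peak_uA_cm2", "count", "cv_isi", "regular"))
  expect_equal(sweep$count[sweep$peak_uA_cm2 <= 1], c(0, 0))
  expect_true(all(sweep$count[sweep$peak_uA_cm2 >= 12] > 0))
  # threshold structure: a scale s* exists with silence below and firing
  # at 1.5x above (no re-entrant silent band on this grid)
  silent <- max_silent_peak(sweep)
  expect_false(is.na(silent))
  expect_true(all(sweep$count[sweep$peak_uA_cm2 >= 1.5 * silent] > 0))
  expect_true(all(sweep$regular[sweep$peak_uA_cm2 >= 12]))
})

test_that("minimum exposure shrinks with amplitude and flags hopeless stimuli", {
  i_base <- stimulation_current()
  peak <- max(abs(i_base$values))
  sub <- waveform(i_base$time, i_base$values / peak, unit = "uA/cm2")
  out <- min_exposure_for_spike(sub, sim_ms = 100)
  expect_true(is.na(out))
  expect_match(attr(out, "reason"), "no spike")
  # strong stimulus: a couple of milliseconds suffice (fast charging)
  strong <- waveform(i_base$time, i_base$values / peak * 90, unit = "uA/cm2")
  t_strong <- min_exposure_for_spike(strong, sim_ms = 100)
  mid <- waveform(i_base$time, i_base$values / peak * 9, unit = "uA/cm2")
  t_mid <- min_exposure_for_spike(mid, sim_ms = 100)
  expect_lte(t_strong, 2)
  expect_lte(t_strong, t_mid)
})
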
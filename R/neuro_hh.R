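#' Hodgkin-Huxley membrane parameters
#'
#' Canonical squid-axon parameter set: membrane capacitance in uF/cm^2,
#' maximal conductances in mS/cm^2, Nernst/leak potentials in mV.  The
#' gating kinetics use the standard alpha/beta rate expressions; the
#' resting potential is approximately -65 mV.
#'
#' @param Cm Membrane capacitance, uF/cm^2.
#' @param gbar_K,gbar_Na,gL Maximal K+, Na+ and leak conductances, mS/cm^2.
#' @param VK,VNa,VL Reversal potentials, mV (`VK < VL < VNa`).
#' @return Object of class `hh_params`.
#' @export
hh_params <- function(Cm = 1, gbar_K = 36, gbar_Na = 120, gL = 0.3,
                      VK = -77, VNa = 50, VL = -54.4) {
  stopifnot(Cm > 0, gbar_K >= 0, gbar_Na >= 0, gL >= 0)
  if (!(VK < VL && VL < VNa)) stop("require VK < VL < VNa")
  structure(list(Cm = Cm, gbar_K = gbar_K, gbar_Na = gbar_Na, gL = gL,
                 VK = VK, VNa = VNa, VL = VL),
            class = "hh_params")
}

.hh_param_vec <- function(p) {
  c(p$Cm, p$gbar_K, p$gbar_Na, p$gL, p$VK, p$VNa, p$VL)
}

#' Stimulus interface specification
#'
#' Parameters of the electrical interface between the shell surface and
#' the membrane: the ohmic interface resistance (the static resistance
#' between two surface electrodes is in the 0.45-1 MOhm range), an
#' effective membrane area for current-density normalization, the
#' RF-removal low-pass cutoff, the time-scaling factor mapping the
#' 62 MHz difference tone to 62 Hz, and an amplitude divisor.
#'
#' The effective area is a calibration knob: the default of 1e-8 cm^2 (a
#' one-square-micrometre contact patch) puts the unscaled interface
#' current of the default chain in the tens of uA/cm^2 regime that the
#' amplitude sweep explores; absolute amplitude calibration is
#' deliberately left to the `amplitude_scale` sweep.
#'
#' @param interface_resistance Interface resistance, Ohm.
#' @param effective_area Effective membrane area, cm^2.
#' @param lowpass_cutoff Low-pass cutoff, Hz (on the fast time axis).
#' @param lowpass_method Filter design passed to [lowpass()]; the default
#'   `"spectral"` isolates the demodulated band completely, which the
#'   stimulation stage requires because the difference-frequency
#'   component lies orders of magnitude below the carriers.
#' @param time_scale_factor Time-dilation factor (default 1e6).
#' @param amplitude_scale Amplitude divisor (default 1).
#' @param exposure_ms Stimulus exposure (rescaled axis), ms; `Inf` keeps
#'   the full record.
#' @return Object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(interface_resistance = 0.45e6,
                          effective_area = 1e-8,
                          lowpass_cutoff = 100e6,
                          lowpass_method = "spectral",
                          time_scale_factor = 1e6,
                          amplitude_scale = 1,
                          exposure_ms = Inf) {
  stopifnot(interface_resistance > 0, effective_area > 0,
            lowpass_cutoff > 0, time_scale_factor > 0,
            amplitude_scale > 0, exposure_ms > 0,
            lowpass_method %in% c("spectral", "butterworth"))
  structure(list(interface_resistance = interface_resistance,
                 effective_area = effective_area,
                 lowpass_cutoff = lowpass_cutoff,
                 lowpass_method = lowpass_method,
                 time_scale_factor = time_scale_factor,
                 amplitude_scale = amplitude_scale,
                 exposure_ms = exposure_ms),
            class = "stimulus_spec")
}

#' Interface current density from a surface potential record
#'
#' Ohm's law across the interface resistance, normalized by the
#' effective membrane area: `i = V0 / R / A`, reported in uA/cm^2.
#'
#' @param V0 A [waveform()] of surface potential difference, V.
#' @param spec A [stimulus_spec()].
#' @return A [waveform()] in uA/cm^2.
#' @export
interface_current <- function(V0, spec = stimulus_spec()) {
  stopifnot(inherits(V0, "waveform"), inherits(spec, "stimulus_spec"))
  i <- V0$values / spec$interface_resistance / spec$effective_area * 1e6
  waveform(V0$time, i, unit = "uA/cm2", label = "interface current density")
}

#' Zero-phase low-pass filter
#'
#' Two zero-phase designs.  `"butterworth"` (default order 4) is applied
#' forward and backward; DC gain is unity and one octave above the
#' cutoff the two-pass attenuation of the default order exceeds 40 dB.
#' `"spectral"` applies an ideal frequency-domain mask with a
#' raised-cosine transition from the cutoff to 1.1x the cutoff, which
#' suppresses out-of-band tones completely; it is the right tool when a
#' weak in-band component must be isolated under carriers only a fraction
#' of an octave above the cutoff, where a low-order Butterworth skirt
#' still leaks.
#'
#' @param w A [waveform()].
#' @param cutoff Cutoff frequency, Hz (must be below Nyquist).
#' @param order Butterworth order per pass.
#' @param method `"butterworth"` or `"spectral"`.
#' @return Filtered [waveform()].
#' @export
lowpass <- function(w, cutoff, order = 4L,
                    method = c("butterworth", "spectral")) {
  stopifnot(inherits(w, "waveform"), cutoff > 0)
  method <- match.arg(method)
  fs <- sample_rate(w)
  if (cutoff >= fs / 2)
    stop("cutoff must lie below the Nyquist frequency")
  x <- w$values
  n <- length(x)
  if (method == "butterworth") {
    bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
    # symmetric-reflection padding: the double pass starts from zero
    # state, so without padding the start-up transient corrupts both
    # ends; even reflection continues an oscillation exactly when the
    # record begins or ends on an extremum and adds no spurious
    # low-frequency content
    k <- min(n - 1, ceiling(6 * fs / cutoff))
    head_pad <- x[(k + 1):2]
    tail_pad <- x[(n - 1):(n - k)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y <- y[(k + 1):(k + n)]
  } else {
    # circular mask: intended for records that hold an integer number of
    # periods of every tone (the drive generator's commensurate records),
    # where each component sits on an exact bin and the mask separates
    # bands with neither leakage nor edge ringing
    f <- (0:(n - 1)) / n * fs
    f <- pmin(f, fs - f)                    # two-sided frequency axis
    gain <- rep(0, n)
    gain[f <= cutoff] <- 1
    trans <- f > cutoff & f < 1.1 * cutoff
    gain[trans] <- 0.5 * (1 + cos(pi * (f[trans] - cutoff) / (0.1 * cutoff)))
    y <- Re(fft(fft(x) * gain, inverse = TRUE)) / n
  }
  waveform(w$time, y, unit = w$unit,
           label = paste0(w$label, " (lowpass ", signif(cutoff, 3), " Hz)"))
}

#' Rescale the time axis of a waveform
#'
#' Time dilation `t -> factor * t`; sample values are unchanged, so a
#' component at 62 MHz becomes one at 62 Hz under `factor = 1e6`.
#'
#' @param w A [waveform()].
#' @param factor Positive dilation factor.
#' @return Rescaled [waveform()].
#' @export
time_rescale <- function(w, factor) {
  stopifnot(inherits(w, "waveform"), factor > 0)
  waveform(w$time * factor, w$values, unit = w$unit, label = w$label)
}

#' Integrate the Hodgkin-Huxley membrane response
#'
#' Fixed-step fourth-order Runge-Kutta integration (compiled kernel) of
#' the membrane equation with voltage-gated Na+/K+ channels and leak,
#' driven by a sampled current-density stimulus (linearly interpolated,
#' zero outside the record).  Gates are governed purely by their
#' dynamics and stay in [0, 1].
#'
#' @param i_ind A [waveform()] of current density, uA/cm^2, with time
#'   axis in seconds (the rescaled, biological axis).
#' @param params An [hh_params()].
#' @param v0 Initial membrane potential, mV; gates start at their
#'   steady-state values for `v0`.
#' @param duration_ms Simulated duration, ms.
#' @param dt_ms Integration step, ms (<= 0.01 recommended).
#' @param store_every Store every k-th step (thins the output trace).
#' @return Object of class `hh_trace`: list with `time_ms`, `v_m`,
#'   gates `n`, `m`, `h`, and the integration step.
#' @export
hh_simulate <- function(i_ind = NULL, params = hh_params(), v0 = -65,
                        duration_ms = 500, dt_ms = 0.01,
                        store_every = 1L) {
  stopifnot(inherits(params, "hh_params"), duration_ms > 0, dt_ms > 0,
            dt_ms <= 0.01 + 1e-12)
  if (is.null(i_ind)) {
    st_t <- c(0, duration_ms)
    st_i <- c(0, 0)
  } else {
    stopifnot(inherits(i_ind, "waveform"))
    st_t <- i_ind$time * 1e3   # s -> ms
    st_i <- i_ind$values
  }
  m <- .hh_rk4_cpp(st_t, st_i, duration_ms, dt_ms,
                   .hh_param_vec(params), v0, as.integer(store_every))
  structure(list(time_ms = m[, 1], v_m = m[, 2],
                 n = m[, 3], m = m[, 4], h = m[, 5],
                 dt_ms = dt_ms, params = params),
            class = "hh_trace")
}

#' @export
print.hh_trace <- function(x, ...) {
  cat(sprintf("<hh_trace> %d samples over %.4g ms, v_m in [%.1f, %.1f] mV\n",
              length(x$time_ms), max(x$time_ms), min(x$v_m), max(x$v_m)))
  invisible(x)
}

#' Resting state of the membrane
#'
#' Relaxes the unstimulated membrane for `settle_ms` and returns the
#' final state (the resting fixed point).
#'
#' @param params An [hh_params()].
#' @param settle_ms Relaxation time, ms.
#' @return List with `v`, `n`, `m`, `h`.
#' @export
hh_rest <- function(params = hh_params(), settle_ms = 500) {
  tr <- hh_simulate(NULL, params, v0 = -65, duration_ms = settle_ms,
                    store_every = 100L)
  k <- length(tr$time_ms)
  list(v = tr$v_m[k], n = tr$n[k], m = tr$m[k], h = tr$h[k])
}

#' Detect action potentials by threshold crossing
#'
#' Upward crossings of the voltage threshold separated by at least the
#' refractory interval.
#'
#' @param trace An [hh_simulate()] result.
#' @param threshold Detection threshold, mV (default 0).
#' @param refractory_ms Minimum inter-spike separation, ms (default 2).
#' @return Object of class `spike_train`: list with `spike_times` (ms),
#'   `count`, `isi` (ms), `cv_isi`, and `regular` (CV of ISI < 0.1).
#' @export
detect_spikes <- function(trace, threshold = 0, refractory_ms = 2) {
  stopifnot(inherits(trace, "hh_trace"))
  v <- trace$v_m
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold)
  times <- trace$time_ms[up + 1]
  keep <- logical(length(times))
  last <- -Inf
  for (i in seq_along(times)) {
    if (times[i] - last >= refractory_ms) {
      keep[i] <- TRUE
      last <- times[i]
    }
  }
  times <- times[keep]
  isi <- diff(times)
  cv <- if (length(isi) >= 2) sd(isi) / mean(isi) else NA_real_
  structure(list(spike_times = times, count = length(times),
                 isi = isi, cv_isi = cv,
                 regular = isTRUE(cv < 0.1)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", x$count))
  if (x$count >= 3)
    cat(sprintf(", mean ISI %.2f ms, CV %.3f, regular = %s",
                mean(x$isi), x$cv_isi, x$regular))
  cat("\n")
  invisible(x)
}

#' Demodulated stimulation current of the full chain
#'
#' Builds the membrane stimulus from the transduction chain: two-tone
#' drive -> nonlinear core strain -> shell stress -> open-circuit axial
#' field -> surface potential over the electrode pair -> interface
#' current.  The static (pre-drive) bias contribution is subtracted: the
#' standing bias strain exists before the AC drive is switched on and,
#' with the finite shell conductivity, sustains no interface current;
#' only the drive-induced part stimulates.  The current is then low-pass
#' filtered on the fast axis (RF removal) and the time axis dilated by
#' the time-scale factor.  The sign is normalized so that the dominant
#' lobe is depolarizing (electrode orientation is arbitrary).
#'
#' @param spec A [drive_spec()].  The default record holds 93 beat
#'   periods: that is an exact number of full periods of the two-tone
#'   drive (whose fundamental is the 2 MHz tone spacing, 31 beats per
#'   period), so every spectral component sits on an FFT bin for the
#'   band-isolation filter, and the record dilates to 1.5 s, fully
#'   covering a one-second membrane simulation.
#' @param core_mat,shell_mat,geom Chain components.
#' @param stim A [stimulus_spec()].
#' @param resonator Optional [resonator_spec()].
#' @param electrode_separation Readout electrode separation, m.
#' @return A [waveform()] of current density (uA/cm^2) on the rescaled
#'   (biological) time axis in seconds.
#' @export
stimulation_current <- function(spec = drive_spec(duration = 93 / 62e6),
                                core_mat = metglas_material(),
                                shell_mat = aln_material(),
                                geom = core_shell_geometry(),
                                stim = stimulus_spec(),
                                resonator = NULL,
                                electrode_separation = 3e-6) {
  drive <- synthesize_drive(spec)
  core <- transduce(drive, core_mat, resonator)
  # axial strain pattern of the macrospin: eps = lambda * (-1/2,-1/2,1,0,0,0)
  unit_eps <- c(-0.5, -0.5, 1, 0, 0, 0)
  kE <- open_circuit_field(
    shell_stress_from_strain(unit_eps, geom, shell_mat), shell_mat)[3]
  lam_bias <- {
    st <- self_consistent_state(c(0, 0, spec$bias_B / .mu0), mat = core_mat)
    st$strain_me[3]
  }
  V0 <- surface_potential(kE * (core$strain$values - lam_bias),
                          electrode_separation)
  v_wave <- waveform(drive$time, V0, unit = "V",
                     label = "surface potential difference")
  i_fast <- interface_current(v_wave, stim)
  i_filt <- lowpass(i_fast, stim$lowpass_cutoff,
                    method = stim$lowpass_method)
  i_slow <- time_rescale(i_filt, stim$time_scale_factor)
  vals <- i_slow$values / stim$amplitude_scale
  if (max(vals) < -min(vals)) vals <- -vals
  waveform(i_slow$time, vals, unit = "uA/cm2",
           label = "demodulated stimulation current")
}

#' Amplitude-scaling sweep of the membrane response
#'
#' Runs the membrane simulation for each amplitude divisor and tabulates
#' the peak current density, the spike count, and the regularity of the
#' spike train.  Deterministic.
#'
#' @param i_base Base stimulus [waveform()] (uA/cm^2, time in s).
#' @param scales Positive divisors applied to the base amplitude.  Use
#'   `peaks` instead to sweep absolute peak amplitudes.
#' @param peaks Optional grid of absolute peak current densities,
#'   uA/cm^2; overrides `scales`.
#' @param params An [hh_params()].
#' @param duration_ms Simulated duration per amplitude, ms.
#' @param dt_ms Integration step, ms.
#' @param threshold,refractory_ms Spike-detection settings.
#' @return Data frame with columns `scale`, `peak_uA_cm2`, `count`,
#'   `cv_isi`, `regular`.
#' @export
amplitude_sweep <- function(i_base, scales = NULL, peaks = NULL,
                            params = hh_params(),
                            duration_ms = 1000, dt_ms = 0.01,
                            threshold = 0, refractory_ms = 2) {
  stopifnot(inherits(i_base, "waveform"))
  base_peak <- max(abs(i_base$values))
  if (!is.null(peaks)) {
    stopifnot(all(peaks > 0))
    scales <- base_peak / peaks
  }
  stopifnot(!is.null(scales), all(scales > 0))
  rows <- lapply(scales, function(sc) {
    w <- waveform(i_base$time, i_base$values / sc, unit = i_base$unit)
    tr <- hh_simulate(w, params, duration_ms = duration_ms, dt_ms = dt_ms,
                      store_every = 5L)
    sp <- detect_spikes(tr, threshold, refractory_ms)
    data.frame(scale = sc, peak_uA_cm2 = base_peak / sc,
               count = sp$count, cv_isi = sp$cv_isi,
               regular = sp$regular)
  })
  out <- do.call(rbind, rows)
  out[order(out$peak_uA_cm2), , drop = FALSE]
}

#' Breakpoints of an amplitude sweep
#'
#' `max_silent_peak` returns the largest peak amplitude producing zero
#' spikes.  `plateau_onset` returns the smallest peak amplitude from
#' which the spike count is constant and the inter-spike-interval
#' coefficient of variation stays below `cv_max` for all larger
#' amplitudes on the grid (the stable, temporally consistent plateau).
#'
#' @param sweep An [amplitude_sweep()] result.
#' @param cv_max Regularity ceiling on the ISI CV (default 0.1).
#' @return Peak amplitude, uA/cm^2 (NA if the structure is absent).
#' @export
max_silent_peak <- function(sweep) {
  z <- sweep$peak_uA_cm2[sweep$count == 0]
  if (!length(z)) NA_real_ else max(z)
}

#' @rdname max_silent_peak
#' @export
plateau_onset <- function(sweep, cv_max = 0.1) {
  s <- sweep[order(sweep$peak_uA_cm2), ]
  n <- nrow(s)
  final_count <- s$count[n]
  if (final_count == 0) return(NA_real_)
  ok <- s$count == final_count & !is.na(s$cv_isi) & s$cv_isi < cv_max
  # smallest index from which ok holds for every larger amplitude
  from <- n
  while (from > 1 && ok[from - 1]) from <- from - 1
  if (!ok[from]) return(NA_real_)
  s$peak_uA_cm2[from]
}

#' Minimum exposure time to elicit a spike
#'
#' Truncates the stimulus after an exposure `T` (zero afterwards),
#' simulates the membrane, and bisects on `T` for the smallest exposure
#' that yields at least one spike.
#'
#' @param i_base Stimulus [waveform()] (uA/cm^2, time in s).
#' @param params An [hh_params()].
#' @param sim_ms Simulated duration per trial, ms.
#' @param resolution_ms Bisection resolution, ms.
#' @param dt_ms Integration step, ms.
#' @param threshold,refractory_ms Spike-detection settings.
#' @return Minimum exposure, ms, or `NA` with attribute
#'   `reason = "no spike at any exposure <= duration"` for stimuli that
#'   never spike.
#' @export
min_exposure_for_spike <- function(i_base, params = hh_params(),
                                   sim_ms = 200, resolution_ms = 0.5,
                                   dt_ms = 0.01,
                                   threshold = 0, refractory_ms = 2) {
  stopifnot(inherits(i_base, "waveform"))
  spikes_with_exposure <- function(T_ms) {
    vals <- ifelse(i_base$time * 1e3 <= T_ms, i_base$values, 0)
    w <- waveform(i_base$time, vals, unit = i_base$unit)
    tr <- hh_simulate(w, params, duration_ms = sim_ms, dt_ms = dt_ms,
                      store_every = 5L)
    detect_spikes(tr, threshold, refractory_ms)$count
  }
  hi <- min(sim_ms, max(i_base$time) * 1e3)
  if (spikes_with_exposure(hi) < 1) {
    return(structure(NA_real_,
                     reason = "no spike at any exposure <= duration"))
  }
  lo <- 0
  while (hi - lo > resolution_ms) {
    mid <- (lo + hi) / 2
    if (spikes_with_exposure(mid) >= 1) hi <- mid else lo <- mid
  }
  hi
}
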
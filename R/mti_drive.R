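#' Two-tone coil drive specification
#'
#' Describes the external excitation applied to the device: a DC flux
#' density bias plus two sinusoidal magnetic tones at `f1` and `f2`
#' produced by the symmetric coil pair.  The default tones are the two
#' mechanical-resonance drive frequencies 126 and 188 MHz, giving a beat
#' (difference) frequency of 62 MHz.
#'
#' The sampling defaults keep the difference tone on a clean part of the
#' spectrum: `sample_rate = 16 f2` and `duration = 20 / |f2 - f1|`
#' (20 beat periods).  The time step of the original time-domain study,
#' `0.1 * 0.05 / f2`, is available as `preset = "fine"`.
#'
#' @param f1,f2 Tone frequencies, Hz (`f1 != f2`).
#' @param coil_current Coil current amplitude, A.
#' @param coil_radius Coil radius, m.
#' @param coil_separation Coil-pair separation, m (device midway).
#' @param bias_B DC flux-density bias, T.
#' @param duration Record length, s (default 20 beat periods).
#' @param sample_rate Sampling rate, Hz (default `16 * max(f1, f2)`).
#' @param amplitude_override Optional tone amplitude, T; when given, both
#'   tones use it instead of the coil field at the core center.
#' @param preset `"default"` or `"fine"` (time step `0.1 * 0.05 / f2`).
#' @return Object of class `drive_spec`.
#' @export
drive_spec <- function(f1 = 126e6, f2 = 188e6,
                       coil_current = 0.1, coil_radius = 400e-6,
                       coil_separation = 800e-6,
                       bias_B = 0.293,
                       duration = NULL, sample_rate = NULL,
                       amplitude_override = NULL,
                       preset = c("default", "fine")) {
  preset <- match.arg(preset)
  stopifnot(f1 > 0, f2 > 0, f1 != f2, coil_current >= 0,
            coil_radius > 0, coil_separation > 0)
  df <- abs(f2 - f1)
  if (is.null(sample_rate))
    sample_rate <- if (preset == "fine") f2 / (0.1 * 0.05) else 16 * max(f1, f2)
  if (is.null(duration)) duration <- 20 / df
  if (sample_rate <= 4 * max(f1, f2))
    stop("sample_rate must exceed 4 * max(f1, f2) (Nyquist with margin)")
  if (duration < 10 / df)
    stop("duration must cover at least 10 beat periods")
  structure(list(f1 = f1, f2 = f2, coil_current = coil_current,
                 coil_radius = coil_radius,
                 coil_separation = coil_separation,
                 bias_B = bias_B, duration = duration,
                 sample_rate = sample_rate,
                 amplitude_override = amplitude_override),
            class = "drive_spec")
}

#' @export
print.drive_spec <- function(x, ...) {
  cat("<drive_spec>\n")
  cat(sprintf("  tones %.4g / %.4g MHz (beat %.4g MHz), bias %.3g T\n",
              x$f1 / 1e6, x$f2 / 1e6, abs(x$f2 - x$f1) / 1e6, x$bias_B))
  cat(sprintf("  fs = %.4g GHz, duration %.4g us, coil I = %g A, r = %g um\n",
              x$sample_rate / 1e9, x$duration * 1e6, x$coil_current,
              x$coil_radius * 1e6))
  invisible(x)
}

#' On-axis magnetic flux density of a circular current loop
#'
#' `B = mu0 I R^2 / (2 (R^2 + z^2)^(3/2))` along the loop axis.
#'
#' @param current Loop current, A.
#' @param loop_radius Loop radius, m.
#' @param axial_distance Distance from the loop plane along the axis, m.
#' @return Flux density, T.
#' @examples
#' loop_axial_field(0.1, 400e-6, 0)   # field at the loop center
#' @export
loop_axial_field <- function(current, loop_radius, axial_distance) {
  stopifnot(loop_radius > 0)
  .mu0 * current * loop_radius^2 /
    (2 * (loop_radius^2 + axial_distance^2)^1.5)
}

.tone_amplitudes <- function(spec) {
  if (!is.null(spec$amplitude_override)) {
    rep(spec$amplitude_override, 2)
  } else {
    a <- loop_axial_field(spec$coil_current, spec$coil_radius,
                          spec$coil_separation / 2)
    c(a, a)
  }
}

#' Synthesize the applied two-tone drive
#'
#' Deterministic (seedless) construction of the total axial flux density
#' at the device, `B(t) = bias + a1 cos(2 pi f1 t) + a2 cos(2 pi f2 t)`,
#' with tone amplitudes taken from the on-axis coil field at the core
#' center (each coil at half the coil separation) unless overridden.
#'
#' @param spec A [drive_spec()].
#' @return A [waveform()] in T.
#' @export
synthesize_drive <- function(spec) {
  stopifnot(inherits(spec, "drive_spec"))
  n <- floor(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  a <- .tone_amplitudes(spec)
  b <- spec$bias_B + a[1] * cos(2 * pi * spec$f1 * t) +
    a[2] * cos(2 * pi * spec$f2 * t)
  waveform(t, b, unit = "T", label = "applied axial flux density")
}

#' Air-medium control signal
#'
#' The same drive passed through a linear, non-magnetostrictive medium,
#' i.e. the identity: the beat is present only as an amplitude envelope
#' and no spectral component exists at the difference frequency.  Used as
#' the negative control for the demodulation analysis.
#'
#' @param spec A [drive_spec()].
#' @return A [waveform()] in T, sample-for-sample equal to
#'   [synthesize_drive()].
#' @export
air_control <- function(spec) {
  w <- synthesize_drive(spec)
  w$label <- "air control (linear medium)"
  w
}
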
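# Shared fixtures: default materials and small drive records built in code.

metglas <- metglas_material()
aln <- aln_material()
geom_default <- core_shell_geometry()
mu0 <- physical_constants()$mu0

# short two-tone drive with explicit tone amplitudes (tests that probe the
# small-signal intermodulation law override the coil-derived amplitudes)
two_tone_drive <- function(a1, a2, bias = 0.293, f1 = 126e6, f2 = 188e6,
                           n_beats = 20, fs = 16 * 188e6) {
  n <- floor(n_beats / abs(f2 - f1) * fs)
  t <- (seq_len(n) - 1) / fs
  waveform(t, bias + a1 * cos(2 * pi * f1 * t) + a2 * cos(2 * pi * f2 * t),
           unit = "T", label = "test drive")
}

# trailing portion of a waveform (settled part, past startup transients)
waveform_tail <- function(w, frac = 0.5) {
  keep <- w$time > max(w$time) * (1 - frac)
  waveform(w$time[keep], w$values[keep], unit = w$unit, label = w$label)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected), tol * abs(expected))
}
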
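---
title: "Methods: a reduced-order magnetoelectric temporal-interference chain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a reduced-order magnetoelectric temporal-interference chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memti)
```

`memti` models the full signal chain of a magnetoelectric core-shell
microdevice used as a local demodulator for magnetic temporal
interference: coil drive → nonlinear magnetostrictive core → piezoelectric
shell → interface current → Hodgkin–Huxley membrane. This vignette records
the model, its assumptions, the parameters that matter, and the numerical
and design choices — including the places where the design was genuinely
open and what we decided.

## The macro-spin reduction

The central fidelity reduction is spatial: the spherical core is treated
as a single uniformly magnetized domain ("macro-spin") instead of a
spatially resolved magnetoelastic continuum. For a sphere this is better
than it sounds, because a uniformly magnetized sphere has an exactly
uniform demagnetizing field, `H_internal = H_applied − M/3`. The
self-consistent state solved by `self_consistent_state()` combines three
relations:

* the anhysteretic Langevin magnetization
  `M = Ms L(3 χ0 |H_eff|/Ms) Ĥ_eff` — remanence is fixed at zero, so there
  is no hysteresis by construction;
* the sphere demagnetization above;
* a magnetoelastic stress correction
  `H_eff = H_internal + 3 λs/(μ0 Ms²) S M`.

Two interpretation choices were open and are fixed as follows. First, the
Langevin argument carries the scaling `3 χ0 / Ms` so that the small-field
slope `dM/dH` equals the tabulated initial susceptibility `χ0 = 200`;
without some slope parameter the tabulated susceptibility would be unused
and the initial slope pinned at 1. Second, the permeability constant in
the stress term is read as the vacuum permeability `μ0` — the only reading
that is dimensionally consistent.

The magnetostrictive strain is isotropic and quadratic,
`ε_me = (3/2)(λs/Ms²) dev(M⊗M)`: traceless, even in `M`, saturating at the
tabulated `λs = 12 ppm` parallel strain. Evenness in `M` is the property
the whole device concept rests on — a quadratic transducer multiplies its
two drive tones and generates the difference frequency.

**Bias-axis convention.** Reported bias values are the applied flux
density `B = μ0 H_applied`, before demagnetization. On this convention the
bias sweep places the magnetostrictivity maximum `dλ/dB` near 0.24 T with
a half-maximum window of roughly 0.11–0.30 T: the knee is set by the
demagnetizing field, since saturation requires
`H_applied ≈ Ms/3` (`μ0 Ms/3 ≈ 0.29 T`). The configured operating bias of
293 mT is carried as a configuration default of the reference device
rather than as a model prediction; it sits inside the window the model
itself produces.

**Fixed-point damping.** The Picard iteration for the self-consistent
state has slope about `−χ0 N` at its steepest point (`N = 1/3`), i.e.
about −67 for this material, so a fixed damping of 0.5 diverges. The
damping is capped at `1.5 / (1 + χ0 (N + |k_stress|))`, which makes the
damped iteration a contraction everywhere; convergence is declared at a
residual of `1e-10 · Ms`, with 10 000 iterations as a hard cap.

## The synthetic drive

`synthesize_drive()` is the package's data generator: it constructs
exactly the excitation the analysis assumes — a DC flux-density bias plus
two equal-amplitude tones
`B(t) = B_bias + a1 cos 2π f1 t + a2 cos 2π f2 t` — and nothing else. Tone
amplitudes come from the on-axis field of a circular loop
(`μ0 I R²/2(R²+z²)^{3/2}`) evaluated at the core center, with each coil at
half the 800 μm separation. The coil radius is not part of the reference
parameter set; 400 μm (the same order as the separation) is the default,
and since only the amplitude *ratio* matters for the demodulation
demonstrations, an `amplitude_override` is provided for absolute control.
With 100 mA drive the default tone amplitude is ≈ 56 μT against a 293 mT
bias — deep in the small-signal regime of the bias curve.

Defaults: `sample_rate = 16 f2` (≈ 3 GHz, four times the Nyquist margin
the validator enforces) and `duration = 20` beat periods (323 ns). The
reference time-domain step `0.1 × 0.05 / f2` is available as a preset. The
drive is deterministic and seedless — repeated calls are bit-identical.

What the generator deliberately does *not* emulate: off-axis field
components, coil impedance, eddy currents in the core, thermal noise, and
any spatial nonuniformity over the particle. Tests that pass on this drive
therefore establish the demodulation mechanism and its scaling laws, not
absolute field magnitudes in tissue.

## Transduction and spectral analysis

`transduce()` maps the drive sample-by-sample through the static
constitutive chain (quasi-static approximation: magnetization follows the
field instantaneously; the fixed point is warm-started from the previous
sample in the compiled kernel). The demodulation mechanism is the static
quadratic nonlinearity; mechanical resonance only rescales amplitudes, so
a single-mode resonator (`resonator_spec()`) — a driven damped harmonic
oscillator integrated by RK4 at the drive rate — is offered as an option
with `Q = 1/(2 η_mech) = 5000` from the tabulated loss of 1e-4, but is
disabled by default. At resonance its gain approaches `Q` once the
transient (time constant `2Q/ω0`) has settled, which is the property the
test suite checks at small `Q`.

The PSD (`power_spectrum()`) is a Hann-windowed one-sided periodogram,
zero-padded to the next power of two, with the *window-weighted* mean
removed: with an ordinary mean the windowed residual DC of a record
holding a non-integer number of tone periods leaks into the low bins at
exactly the level of the demodulated component. The Parseval ratio
(integrated PSD over windowed mean square) is stored with every spectrum
and asserted to 1 % in the tests. Peak prominence is measured against the
median PSD in a band of ±10 % around the difference frequency (widened to
at least ±15 bins), excluding ±3 bins around the candidate peak, the drive
tones, their second harmonics and the sum frequency; 20 dB over that floor
counts as detection. The narrow-band helper `tone_amplitude()` uses a
Hann-windowed complex projection for the same leakage reason.

## Eigenmodes

`sphere_mode_frequencies()` solves the classical free-vibration problem of
a homogeneous isotropic elastic sphere: the torsional branch
`(l−1) j_l(η) = η j_{l+1}(η)` in `η = ωR/c_s`, and the spheroidal branch
as the 2×2 determinant in `ωR/c_p` and `ωR/c_s` (which reduces at `l = 0`
to the classical breathing-mode equation). Roots are bracketed on a dense
grid (20 000 points per decade per branch and order, `l ≤ 6`), polished by
bisection to 1e-12 relative, and deduplicated at 1e-8. The shell is
ignored in the mode solve: the module's role is the frequency-*selection*
methodology, and no claim is made that the bare-core spectrum reproduces a
core-shell FEM spectrum mode-for-mode. Damping enters as a uniform
structural loss factor, giving every mode `ζ = η_mech/2 = 5e-5`; damping
ratios many orders below that are not reproducible from the stated losses
and are treated as out of scope. Drive-pair selection takes the lowest-ζ
pair separated by at least the requested gap, with deterministic
tie-breaks (lower ζ sum, then lower `f1`, then lower `f2`).

## Piezoelectric coupling

The shell is a thin elastic skin in perfect bonding with the core: the
transferred strain is the core surface strain scaled by `R/(R+t)`, the
shell stress is `c_E ε` with `c_E = s_E⁻¹`, and the open-circuit
(zero-displacement) electric field is `E = −(ε0 ε_T)⁻¹ d σ`. The electrical
boundary condition of the shell surface was an open question; open circuit
is assumed, which maximizes the readout field and matches a floating
particle. The printed AlN matrices are assembled in wurtzite (6mm)
symmetry — `d15 = d24 = −3.8`, `d31 = d32 = −1.9`, `d33 = 5` (pC/N) — and
the two unlabeled shear compliances are assigned `s44 = s55 = 8`,
`s66 = 7.7` (pPa⁻¹), the assignment consistent with the hexagonal identity
`s66 = 2(s11 − s12) = 7.66`; both entries are arguments of
`aln_material()` for users who disagree.

`α_ME` is a two-point central difference of the full static chain at the
operating bias, converted with 1 Oe = 10³/4π A/m. Because every stage
after the magnetization is linear, the bias dependence of `α_ME` is the
bias dependence of `dλ/dB`, and the sweep's argmax colocates with the
magnetostrictivity peak — one of the invariants the test suite checks.
Shell thickness enters only through the geometric transfer factor, so the
non-monotonic FEM thickness optimum is explicitly not reproduced. The
surface readout is modeled as `V0 = E_z × 3 μm` (a configurable electrode
separation), and absolute resonant coupling values are treated as context,
not targets: the quasi-static chain gives ≈ 58 V/(m·Oe) at 293 mT, and the
resonator gain is the exposed knob for matching resonant orders of
magnitude.

## The stimulation stage

The membrane stimulus is built in five steps: (1) the drive-induced part
of the shell potential, (2) Ohmic conversion to a current density, (3)
RF removal, (4) time dilation by 10⁶, (5) amplitude scaling.

**Static-offset subtraction.** The bias alone already strains the core;
that standing strain exists before the AC drive is switched on and, across
a resistive interface (and a shell with finite conductivity), sustains no
current. The chain therefore subtracts the bias-point potential rather
than the record mean, keeping the *demodulation-generated* DC (part of the
drive-on stimulus) while dropping the standing offset. The resulting
stimulus is a raised-cosine bump train at the difference frequency.

**Filter choice.** This was the one place where a pre-registered design
had to be revised on substantive grounds. In this quasi-static chain the
demodulated component is roughly 37 dB below the carriers, so a 4th-order
zero-phase Butterworth at 100 MHz leaves the 126 MHz carrier an order of
magnitude *above* the component of interest — and after time dilation that
residue would sit at 126 Hz, inside the biological band, making the
"demodulated" stimulus mostly carrier feedthrough. Since the purpose of
the stage is to isolate the difference-frequency component, the chain uses
a zero-phase spectral mask (unit gain to the cutoff, raised-cosine
transition to 1.1×, zero beyond) applied to a *commensurate* record: the
stimulus drive holds an exact number of full periods of the two-tone field
(31 beats per 500 ns period; 93 beats by default, dilating to 1.5 s so a
one-second membrane run is fully covered), which puts every component on
an exact FFT bin and makes the mask leakage- and ringing-free.
`lowpass()` still provides the Butterworth design (order 4 by default,
even-reflection padded to suppress the zero-state start-up transient of
the double pass) for general records.

**Membrane model.** Gating kinetics are the canonical squid-axon set
(`Cm = 1 μF/cm²`, `ḡ_Na = 120`, `ḡ_K = 36`, `g_L = 0.3 mS/cm²`,
`V_Na = +50`, `V_K = −77`, `V_L = −54.4 mV`, standard α/β rates, rest
≈ −65 mV): the reference analysis names no rate functions, and this set's
repolarization/depolarization excursions bracket the reported −70 and
+30–40 mV levels. Integration is fixed-step RK4 in compiled code at
10 μs (the tests verify spike counts are step-halving stable and agree
with an adaptive `deSolve` solution to < 0.5 mV). Spikes are upward
0 mV crossings separated by a 2 ms refractory interval; counts are
invariant to the threshold anywhere in the spike body, which the tests
assert. "Temporally consistent" is operationalized as an
inter-spike-interval coefficient of variation below 0.1 — the reference
analysis does not define its irregularity criterion, so this definition is
the package's own.

**Calibration knobs.** The interface resistance defaults to 0.45 MΩ (the
lower end of the quoted 0.45–1 MΩ static impedance) and the effective
membrane area to 1e-8 cm² (a 1 μm² contact patch), chosen once so that the
unscaled stimulus peaks in the tens of μA/cm²; both are explicit
calibration knobs, and all dosimetry sweeps are parameterized by absolute
peak current density, which removes their influence from the reported
breakpoints. The amplitude sweep itself runs one second of membrane time
per amplitude on a 0.05 μA/cm² grid; the silent/plateau breakpoints are
the largest silent grid amplitude and the smallest amplitude from which
the count stays constant with CV < 0.1 upward. Minimum exposure is found
by bisection (0.5 ms resolution) on truncated stimuli over 200 ms runs.

## Problem sizes and runtime

The default analyses are sized for interactive use: 970-sample
demodulation records (20 beats at 16·f2), 401-point bias sweeps, mode
scans of ~18 000 points per branch and order, 391-amplitude dosimetry
sweeps of 10⁵ RK4 steps each. The full test suite runs in well under a
minute; the end-to-end reproduction script in a few seconds.

## Known limitations

* No spatial resolution: deformation patterns, surface "hotspot" maps and
  mode-shape-dependent readout are outside the model; the electrode pair
  sees the uniform axial field only.
* The quasi-static chain omits resonant amplification unless the
  single-mode resonator is enabled; absolute coupling and surface-field
  magnitudes are therefore lower bounds, not predictions.
* The anhysteretic model has no hysteresis, anisotropy or eddy-current
  loss; bias-curve asymmetries seen in real laminates will not appear.
* The stimulus waveform is a clean raised-cosine bump train; FEM-derived
  or measured waveforms with strong harmonic content shift the
  entrainment (plateau) onset upward relative to this chain.
* Membrane dosimetry uses a point (space-clamped) HH model; extracellular
  field geometry, fiber orientation and temperature corrections are out of
  scope.
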
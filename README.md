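# memti

Reduced-order simulation of magnetoelectric (ME) core-shell microdevices
driven by magnetic temporal interference (MTI), down to the neural response
they can evoke.

## The problem

Wireless neurostimulation with remote coils faces a trade-off: magnetic
fields at frequencies low enough to excite neurons (tens to hundreds of Hz)
are hard to focus and couple weakly, while high-frequency fields penetrate
and couple well but cannot stimulate. Temporal interference sidesteps this
by applying two high-frequency tones at `f1` and `f2` whose beat envelope
oscillates at the difference `Δf = f2 − f1` — but in a linear medium the
beat is only an envelope, not a real spectral component, and cells do not
demodulate it.

A magnetostrictive–piezoelectric core-shell particle can do the
demodulation locally. The magnetostrictive core (MetGlas, a 100 μm sphere)
deforms with the *square* of its magnetization, so two applied tones mix
and a genuine strain component appears at `Δf`. The piezoelectric shell
(AlN, 37.5 μm) converts that strain into a surface electric potential,
which drives an ionic current across the interface to an adjacent cell
membrane. With tones at 126 and 188 MHz, the particle emits a local
electrical signal at 62 MHz; mapped into the biological band, this becomes
a 62 Hz stimulus that elicits well-controlled action potentials.

`memti` implements that whole chain as a desk-scale model for users who
want to explore the mechanism, its operating points, and its dosimetry
without a 3-D multiphysics solver: a uniformly magnetized (macro-spin)
sphere with demagnetizing factor 1/3 replaces the spatial field solve, a
thin-shell transfer factor replaces shell elasticity, and the canonical
Hodgkin–Huxley membrane stands in for the neuron.

## The model

* **Anhysteretic magnetization** (Langevin law, initial susceptibility
  `χ0`, saturation `Ms`):
  `M = Ms · L(3 χ0 |H_eff| / Ms) · Ĥ_eff`, `L(x) = coth x − 1/x`,
  with the internal field `H = H_applied − M/3` of a sphere and a
  magnetoelastic stress correction `H_eff = H + 3λs/(μ0 Ms²) · S M`.
* **Magnetostriction** (isotropic, quadratic, deviatoric):
  `ε_me = (3/2)(λs/Ms²) · dev(M ⊗ M)`, saturating at `λs = 12 ppm`.
  The quadratic dependence is the demodulator: the strain response to
  `a1 cos ω1 t + a2 cos ω2 t` contains a component at `|ω2 − ω1|`
  proportional to `a1 a2`.
* **Piezoelectric readout** (strain-charge form, open circuit):
  `σ_shell = c_E · (R/(R+t)) ε_core`, `E = −(ε0 ε_T)⁻¹ d σ`, and the
  ME coupling coefficient `α_ME = dE/dH` in V/(m·Oe).
* **Elastic eigenmodes** of the free core sphere (torsional and spheroidal
  branches, spherical Bessel characteristic equations) select drive
  frequencies with low damping ratio `ζ = Im f / |f|`.
* **Neural response**: the interface current
  `i = V0 / (R_interface · A)` is low-pass filtered at 100 MHz, time-scaled
  by 10⁶ (62 MHz → 62 Hz), and injected into the Hodgkin–Huxley membrane
  equation `Cm dv/dt = i_ind − ḡ_K n⁴(v−V_K) − ḡ_Na m³h(v−V_Na) − g_L(v−V_L)`.

## Worked example

```r
library(memti)

# 1. Two-tone demodulation: nonlinear core vs. linear air control
demodulation_report()
#> <demodulation_report>
#>   difference frequency |f2 - f1| = 62 MHz
#>   core : peak at 61.69 MHz, prominence 30.1 dB, found = TRUE
#>   air  : peak at 58.75 MHz, prominence 3.7 dB, found = FALSE
#>   contrast verdict: TRUE
```

The strain spectrum of the core shows the demodulated 62 MHz component
(61.69 MHz is the nearest FFT bin) standing 30 dB above the local spectral
floor; the identical drive passed through a linear medium shows nothing at
the difference frequency — the mixing is a property of the material, not
of the applied field.

```r
# 2. Operating point: bias sweep and coupling
bias_sweep()
#> <bias_curve> 401 bias points
#>   optimum bias 0.245 T, half-maximum slope window [0.110, 0.300] T
#>   lambda range [0, 1.2e-05]
me_coefficient_at_bias(0.293)
#> [1] 57.73963
```

The magnetostrictivity `dλ/dB` peaks near 0.24 T — inside the 200–350 mT
operating window — because the sphere's demagnetizing field dominates the
approach to saturation (`μ0 Ms / 3 ≈ 0.29 T`). The small-signal coupling at
the 293 mT operating bias is ≈ 58 V/(m·Oe) for the quasi-static chain.

```r
# 3. Demodulated stimulus and spike dosimetry
i <- stimulation_current()
sweep <- amplitude_sweep(i, peaks = c(2, 3, 6, 10, 15), duration_ms = 1000)
sweep
#>      scale peak_uA_cm2 count     cv_isi regular
#>  12.892011           2     0         NA   FALSE
#>   8.594674           3    31 0.02335590    TRUE
#>   4.297337           6    63 0.01140030    TRUE
#>   2.578402          10    63 0.02044904    TRUE
#>   1.718935          15    63 0.02524399    TRUE
```

Below ≈ 2.5 μA/cm² peak current density the membrane stays silent; above
≈ 6 μA/cm² it locks one-to-one to the 62 Hz stimulus (62–63 spikes per
second, inter-spike-interval CV ≈ 0.01–0.03) — the stable, temporally
consistent plateau an implant would be operated on.

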
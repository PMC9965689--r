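---
title: "Methods: models, parameters and design choices in bvic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in bvic}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bvic)
```

## The measurement model

`bvic` implements the computational chain of an impedance-reflection probe
for branch ice content. Branch tissue is treated as a three-phase dielectric
mixture — gas, liquid water, solids — in a lumped equivalent circuit. The
total impedance is taken **exactly in its lumped printed form**

$$Z = (R_g \,\|\, R_l \,\|\, R_s) + j\,\omega\,(C_g + C_l + C_s),$$

and, after substituting the capacitance–permittivity relation
$\varepsilon_r = C/(k\,\varepsilon_0)$, as

$$Z = R + j\,\omega k \varepsilon_0
      \left(\tfrac{V_g}{V}\varepsilon_g + \tfrac{V_l}{V}\varepsilon_l
          + \tfrac{V_s}{V}\varepsilon_s\right),$$

with the *simplified mode* keeping only the liquid term. A deliberate
numerical choice: the imaginary part is proportional to $\omega C$, not
$1/(\omega C)$, as the formula is written in the source material this model
follows. Dimensionally a series-capacitive reading would use $1/(j\omega
C)$, and measured branch reactance below 200 MHz is negative (capacitive),
while this form yields a positive imaginary part. We keep the printed form
because the artifact only requires a *monotone* liquid-water → impedance →
voltage mapping, which it provides; a "physical" $1/(j\omega C)$ mode was
considered and intentionally not added to keep one canonical forward chain.
The sign convention tension is documented here rather than resolved, since
the package's deliverables (calibrated water content, ice content, rates)
are unaffected by it.

The probe converts impedance to an amplified analog voltage through the
reflection coefficient on a 50 Ω coaxial line:

$$U = 2\,\beta_0 A \,\operatorname{Re}\!\frac{Z_P - Z_L}{Z_P + Z_L}.$$

`U` is treated as the signed real projection of the complex reflection
expression — the hardware emits a rectified, amplified DC level, and the
real projection is the scalar that preserves the matched-load zero
(`U = 0` at `Z_P = Z_L`) and the passive bound `|U| ≤ 2β₀A`. The inverse
`impedance_from_voltage()` is restricted to purely resistive loads, where
the inversion is closed-form and unique; it exists for simulator round
trips, not as a claim that the field instrument inverts its own transfer
function.

### Probe constants

| parameter | unit | default | why |
|---|---|---|---|
| `frequency_hz` | Hz | 1e8 | 100 MHz: species variability is low at 100–200 MHz and branch reactance stays capacitive there; 100 MHz is the cheapest crystal in that band |
| `z_line_ohm` | Ω | 50 | standard coaxial line impedance |
| `amplitude_v` | V | 1 | excitation amplitude; free scale, absorbed by calibration |
| `beta0` | — | solved | see below |
| `k_geo_m` | m | 1e-3 | electrode geometry factor; never published for this probe, fixed as a documented config constant |
| `eps_l`, `eps_s`, `eps_g` | — | 81, 3, 1 | liquid water, ice/woody solids, air |

`default_probe_physics()` solves `beta0` (closed form — the output is linear
in it) so that sweeping liquid water from 0 to 100% of the branch volume
spans 1.574 V, the full-scale voltage change recorded when a water sample
freezes completely. With the printed impedance form the reflection real
part responds to the (tiny) imaginary perturbation only at second order, so
the solved `beta0` is large (~8×10⁹); this is a consequence of taking the
formula as printed and is harmless because every downstream quantity is
calibrated. Users with real hardware set `beta0` and `amplitude_v` to their
circuit's values.

## Calibration

`fit_calibration()` is ordinary least squares of volumetric water content
(gravimetric drying-method ground truth) on voltage — the deployed
direction of use, $\theta = kU + b$, not inverse regression. Calibration is
per species/instrument, keyed by a label, because distinct tree species
yield distinct lines. Noiseless linear data are recovered exactly
(`R² = 1`), which the test suite uses as a self-consistency oracle.
Single-pair-per-moisture-level input is assumed; replicate averaging before
fitting, if wanted, is the caller's job.

`apply_calibration()` clamps raw θ outside [0, 100]% instead of erroring,
because field voltages drift slightly outside the calibrated span; the raw
values and a per-element flag are kept as attributes so clamping is always
auditable. A fitted slope indistinguishable from zero triggers a warning:
a flat calibration means the voltage carries no information and must not be
silently inverted downstream.

## The freeze–thaw pipeline

Per sample: calibrate voltage to `theta_pct`; flag `frozen` when ambient
temperature is at or below `freezing_point` (**inclusive** boundary — the
sensor acts when the temperature *reaches* the freezing point; ambient, not
branch, temperature is what the hardware measures); compute ice content
`delta = (theta0 − theta_x) · density_ratio` and the forward-difference
rate `sigma = |Δdelta|/Δt` in %/min (the unit in which freeze–thaw
volatility statistics are quoted). The terminal sample has no later
neighbour and gets `sigma = 0` by convention. `summarize_rates()` uses the
sample (n−1) standard deviation.

| parameter | unit | default | why |
|---|---|---|---|
| `freezing_point` | °C | 0 | pure-water freezing point; supercooling not modelled |
| `density_ratio` | — | 0.917 | ρice/ρwater = 917/1000 kg·m⁻³; the densities themselves are standard values |
| `baseline_window` | samples | 3 | trailing pre-freeze mean for θ0; suppresses single-sample noise without reaching far back in time |
| `clamp_negative_ice` | — | TRUE | noise can push θx above θ0; negative ice is unphysical, clamped and counted |
| `thaw_end_tol` | % | 0.05 | episode-end threshold = the sensor resolution |

**Freeze episodes (a design decision the pipeline owns).** Ice does not
vanish the instant air temperature rises above 0 °C: thawing proceeds while
the frozen flag is already false. Zeroing `delta` outside frozen samples
would therefore discard exactly the thaw dynamics the instrument is built
to show, and would make ground-truth recovery on simulated runs impossible
at the sensor's resolution. The pipeline instead tracks *episodes*: an
episode opens at a frozen-flag onset (θ0 from the trailing window before
the onset, or from an explicit `theta0` if the series starts frozen) and
stays open through the thaw until raw `delta` decays below `thaw_end_tol`.
Between episodes `delta` is 0. Each new onset re-establishes θ0 — the
answer we adopt to the open question of re-baselining across multiple
freeze events in one winter; every baseline is recorded in the output's
`baselines` attribute, so the behaviour is inspectable.

Degenerate inputs: a series frozen from its first sample has no baseline
and errors with an instruction to pass `theta0`; duplicate timestamps error
with the row; a single-sample series is processed (one record, zero rate).

## The synthetic-experiment simulator

The simulator stands in for the freeze–thaw chamber and the field logger.
It generates (i) temperature protocols — the chamber staircases (20 → −16 →
20 °C at 3 °C per 10 min; 20 → −20 → 20 °C at 2 °C per 10 min) and a
diurnal sinusoid for field scenarios; (ii) phase dynamics: the frozen
fraction relaxes first-order toward a temperature-dependent equilibrium
(0 above the freezing point, `1 − unfrozen_fraction_min` below); and (iii)
voltages, by default by inverting the calibration line and adding seeded
Gaussian noise, so pipeline tests are decoupled from physics-mode
decisions; a `"physics"` mode routes through the dielectric-mixture forward
chain instead.

| parameter | unit | default | why |
|---|---|---|---|
| `theta_total` | % | 45 | moisture content of the standard chamber sample |
| `rate_per_min` | 1/min | 0.15 | e-folding ≈ 6.7 min: the frozen fraction follows a 10-min staircase with visible lag, matching the qualitative "slow, then rapid, then stable" trajectory; no kinetic timescale is published, so this is a fixture choice, made once |
| `unfrozen_fraction_min` | — | 0.1 | bound water in woody tissue never freezes entirely |
| `noise_sd_v` | V | 0.002 | ≈ 2.5 ADC steps (0.0008 V) — realistic quantization-plus-electronics noise |
| `sample_minutes` | min | 1 | indoor cadence; field deployments log every 10 min |

The dynamics are a *fixture generator, not a freezing model*: no
supercooling hysteresis, no nucleation stochasticity, no radial
heterogeneity, no latent-heat feedback on temperature. Consequently a green
end-to-end test establishes that the pipeline inverts what the simulator
encodes (calibration, thresholding, baselining, episode bookkeeping,
differencing) at the stated noise level — it does **not** validate the
sensor physics against real branches, which requires hardware.

## Numerical choices and tolerances

- Mass conservation is exact by construction in the simulator
  (`theta_liquid + delta_true/density_ratio = theta_total`) and exact up to
  float rounding in the pipeline on active records
  (`delta/density_ratio + theta_x = theta0`); tests assert 1e-9.
- Round-trip inversion of the reflection function is asserted at 1e-9
  relative on resistive grids; the full-span `beta0` solve is asserted at
  1e-6 relative because the reflection real part sits on an O(1) offset and
  cancellation costs ~9 digits.
- The characterization chain deliberately uses the **2-decimal rounded**
  sensitivity factor (63.53 %/V) for downstream resolution and
  environmental-error arithmetic, because that is how the printed chain is
  computed; the unrounded value is always returned alongside. Coverage
  areas use a configurable `pi_value` with paper-compat 3.14 required to
  reproduce 791.28/3165.12 mm² exactly; `pi` is the default elsewhere.
- The energy index `Kw = (Uc − Ux)/(Uc − U0)·100` flags values outside
  [0, 100]% with a warning instead of clamping: out-of-range Kw is a
  diagnostic of drifted references, not a value to hide.
- Timestamps are ISO-8601 UTC in files and POSIXct/epoch internally, making
  Δt arithmetic unambiguous; CSV dialect is fixed (comma, header, `.`
  decimal) with no sniffing.

## Known limitations

- The printed lumped impedance form is dimensionally loose (see above); the
  package is faithful to it rather than to circuit theory.
- No gap-filling or resampling: irregular series are differenced with their
  actual Δt, nothing more.
- No supercooling-point detection, no embolism inference, no
  temperature-compensated or multi-segment calibration.
- The radial sensitivity limit of the electrode (energy index reaching 0%
  at large branch diameters) is an empirical hardware property; the package
  provides the index arithmetic, not a field model that predicts the limit.
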
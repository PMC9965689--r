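# bvic — branch volumetric ice content sensing toolkit

Overwintering woody plants survive or die by how the liquid water in their
branches converts to ice and back as temperature cycles around the freezing
point. Low-cost impedance-reflection probes make that process observable in
the field: a ring-electrode pair couples a 100 MHz signal into the branch
through its fringing electromagnetic field, and because liquid water
(relative permittivity ≈ 81) dominates the branch's dielectric response
while ice and woody solids sit near ε ≈ 3, the reflected voltage on the
coaxial line tracks the liquid-water volume. `bvic` is an R implementation
of the complete computational chain behind such a sensor, for plant
ecophysiologists and sensor engineers who want to process freeze–thaw time
series, calibrate probes, characterize circuits, or test pipelines against
simulated experiments.

## The model

The branch is an RC mixture of gas/liquid/solid phases with total impedance

    Z = (Rg // Rl // Rs) + j·w·k·ε0·(Vg/V·εg + Vl/V·εl + Vs/V·εs)

which, because the liquid term dominates, simplifies to
`Z = R + j·w·k·ε0·εl·Vl/V`. The probe converts impedance to an amplified
reflection voltage `U = 2·β0·A·(ZP − ZL)/(ZP + ZL)` (line impedance
`ZL = 50 Ω`). A per-species linear calibration `θ = k·U + b` maps voltage to
volumetric water content (%); during a freeze event the ice content and ice
freeze–thaw rate follow from the water-content drop:

    δ  = (θ0 − θx) · ρice/ρwater        (ice content, %)
    σt = |δt' − δt| / |t' − t|          (freeze–thaw rate, %/min)

with `θ0` the pre-freeze baseline, `ρice/ρwater = 0.917`, and freezing
detected from ambient temperature (`T ≤ 0 °C`, inclusive, configurable).

## Worked example

Fit a calibration, simulate a freeze–thaw chamber run (20 → −16 → 20 °C in
3 °C steps every 10 min, 45% volumetric water content, 0.002 V sensor
noise), and process it:

```r
library(bvic)

U <- seq(0.7, 2.0, length.out = 9)
cal <- fit_calibration(
  data.frame(voltage_v = U, theta_pct = 31.28 * U - 6.13),
  species = "Juniperus virginiana")
print(cal)
#> <calibration> Juniperus virginiana: theta = 31.28 * U -6.13  (R^2 = 1.0000)

sim <- simulate_readings(
  simulation_config(protocol = chamber_a_protocol(),
                    noise_sd_v = 0.002, seed = 42), cal)
rec <- process_series(sim$readings, cal)
round(max(rec$delta_pct), 2)
#> [1] 37.3
summarize_rates(rec)
#> Ice freeze-thaw rate (%/min)
#>   Mean Value:         0.33124
#>   Standard Deviation: 0.86965
#>   Minimum Value:      0.00000
#>   Maximum Value:      5.28419
```

The peak ice content of 37.3% is the 45% water content minus the ~10%
residual unfrozen fraction, scaled by the 0.917 density ratio
(45 · 0.9 · 0.917 ≈ 37.1, plus noise). The rate statistics are the four
columns used to compare the freeze–thaw volatility of species with
different cold resistance.

Sensor characterization reproduces the full printed chain:

```r
characterization_report()
#> Sensor characterization
#>   Sensitivity factor: 63.53 %/V (raw 63.532402)
#>   Resolution:         0.05 %
#>   Accuracy:           +/-1.76 %
#>   Env. error bounds:  0.32% to 1.59% (+/-0.635%)
#>   Coverage area (mm^2) by ring dimension (mm):
#>       10 mm      791.28 mm^2
#>       ...
#>       40 mm     3165.12 mm^2
```

i.e. a 1 V output change represents 63.53% ice content, the 0.0008 V ADC
step resolves 0.05%, a 3.52% full-range error is quoted as ±1.76%, ambient
temperature/humidity voltage fluctuation of 0.005–0.025 V corresponds to
0.32–1.59% (±0.635%), and the adjustable 10–40 mm ring electrode covers
791.28–3165.12 mm².

## Command line

```sh
bvic simulate     --config sim.json --out-dir out/ [--seed 7]
bvic calibrate    --pairs pairs.csv --species Juniperus --out cal.json
bvic process      --readings out/readings.csv --calibration cal.json \
                  --out-dir proc/ [--theta0 45]
bvic characterize [--spec spec.json] [--out report.json]
```

(`bvic` is `inst/exec/bvic`; equivalently
`Rscript -e 'quit(status = bvic::bvic_cli())' -- <subcommand> ...`.)

## More

See `vignettes/bvic-methods.Rmd` for the model assumptions, parameter
choices, what the simulator does and does not emulate, and known
limitations.
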
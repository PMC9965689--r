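# Sensor-characterization arithmetic: sensitivity factor, resolution,
# accuracy, environmental error bounds, energy index, conductivity response
# and electrode coverage area.

#' Sensor specification for characterization
#'
#' @param full_span_v Output voltage change over the full 0 to 100% ice sweep
#'   (V); default 1.574, the span measured while a water sample freezes
#'   completely.
#' @param range_pct Measurement range (%); default 100.
#' @param adc_lsb_v Sampling resolution of the analog-to-digital converter
#'   (V); default 0.0008.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(full_span_v = 1.574, range_pct = 100,
                        adc_lsb_v = 0.0008) {
  if (full_span_v <= 0) stop("full_span_v must be > 0", call. = FALSE)
  if (range_pct <= 0) stop("range_pct must be > 0", call. = FALSE)
  if (adc_lsb_v < 0) stop("adc_lsb_v must be >= 0", call. = FALSE)
  structure(list(full_span_v = full_span_v, range_pct = range_pct,
                 adc_lsb_v = adc_lsb_v),
            class = "sensor_spec")
}

#' Sensitivity factor (% ice content per volt)
#'
#' `range_pct / full_span_v`: how much ice content a 1 V output change
#' represents. The 2-decimal rounded value is what feeds the downstream
#' printed characterization chain (resolution, environmental error); the raw
#' value is returned alongside.
#'
#' @param spec A [sensor_spec()].
#' @return List with `rounded` (2 decimals, %/V) and `raw` (%/V).
#' @examples
#' sensitivity_factor(sensor_spec())$rounded # 63.53
#' @export
sensitivity_factor <- function(spec = sensor_spec()) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (spec$full_span_v == 0) stop("zero voltage span", call. = FALSE)
  raw <- spec$range_pct / spec$full_span_v
  list(rounded = round(raw, 2), raw = raw)
}

#' Sensor resolution (%)
#'
#' Smallest detectable ice-content change: the rounded sensitivity factor
#' times the ADC step, reported to 2 decimals.
#'
#' @param spec A [sensor_spec()].
#' @return Resolution (%).
#' @examples
#' resolution(sensor_spec()) # 0.05
#' @export
resolution <- function(spec = sensor_spec()) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (spec$adc_lsb_v == 0) {
    warning("adc_lsb_v is 0: degenerate (infinitely fine) ADC, resolution 0",
            call. = FALSE)
  }
  round(sensitivity_factor(spec)$rounded * spec$adc_lsb_v, 2)
}

#' Accuracy as a plus/minus half range
#'
#' Measurement accuracy is quoted as a symmetric band: half the full-range
#' error.
#'
#' @param full_range_error_pct Maximum error over the measurement range (%),
#'   >= 0.
#' @return Half-range accuracy (±%).
#' @examples
#' accuracy_pm(3.52) # 1.76
#' @export
accuracy_pm <- function(full_range_error_pct) {
  if (any(full_range_error_pct < 0)) {
    stop("full_range_error_pct must be >= 0", call. = FALSE)
  }
  full_range_error_pct / 2
}

#' Environmental error bounds from voltage fluctuation
#'
#' Converts an ambient temperature/humidity-induced output-voltage
#' fluctuation band into water-content terms using the rounded sensitivity
#' factor, and reports the symmetric half-width of the band.
#'
#' @param v_low,v_high Voltage fluctuation bounds (V), `0 <= v_low <= v_high`.
#' @param spec A [sensor_spec()].
#' @return List with `low_pct`, `high_pct` (2 decimals), `halfwidth_pct`
#'   (3 decimals) and the unrounded `raw_low`, `raw_high`, `raw_halfwidth`.
#' @examples
#' env_error_bounds(0.005, 0.025) # 0.32%, 1.59%, +/-0.635%
#' @export
env_error_bounds <- function(v_low, v_high, spec = sensor_spec()) {
  if (v_low < 0 || v_low > v_high) {
    stop("require 0 <= v_low <= v_high", call. = FALSE)
  }
  f <- sensitivity_factor(spec)$rounded
  raw_low <- v_low * f
  raw_high <- v_high * f
  raw_half <- (raw_high - raw_low) / 2
  list(low_pct = round(raw_low, 2), high_pct = round(raw_high, 2),
       halfwidth_pct = round(raw_half, 3),
       raw_low = raw_low, raw_high = raw_high, raw_halfwidth = raw_half)
}

#' Energy index of the radial sensing range
#'
#' Normalized position of a test reading between the water reference (0%)
#' and the air reference (100%):
#' `Kw = (Uc - Ux) / (Uc - U0) * 100`. Used to map how much of the fringing
#' field a branch of a given diameter intercepts; Kw reaching 0% marks the
#' radial sensitivity limit. Values outside \[0, 100\] (a reading drifting
#' outside the references) are flagged with a warning, not clamped.
#'
#' @param Ux Voltage with the test branch in place (V); vectorised.
#' @param U0 Voltage with the probe in air (V).
#' @param Uc Voltage with the probe in water (V); must differ from `U0`.
#' @return Kw (%), with attribute `out_of_range` (logical vector).
#' @export
energy_index <- function(Ux, U0, Uc) {
  if (Uc == U0) {
    stop("degenerate references: Uc must differ from U0", call. = FALSE)
  }
  kw <- (Uc - Ux) / (Uc - U0) * 100
  oor <- kw < 0 | kw > 100
  if (any(oor)) {
    warning(sum(oor), " energy index value(s) outside [0, 100]%: reading(s) ",
            "outside the air/water reference span", call. = FALSE)
  }
  attr(kw, "out_of_range") <- oor
  kw
}

#' Conductivity response delta
#'
#' Signed change of the circuit output at the n-th conductivity gradient
#' relative to the first gradient: `delta_phi_n = Un' - U0'`. Below about
#' 6 mS/cm the circuit output is insensitive to conductivity and the deltas
#' sit at 0.
#'
#' @param Un_prime Output voltage at gradient n (V); vectorised.
#' @param U0_prime Output voltage at the first gradient (V).
#' @return Signed voltage difference (V).
#' @export
conductivity_delta <- function(Un_prime, U0_prime) {
  Un_prime - U0_prime
}

#' Ring-electrode geometry
#'
#' @param ring_dim_mm Printed ring-electrode diameter value (mm); the
#'   adjustable probe spans 10 to 40 mm.
#' @param width_mm Electrode width h (mm); default 12.6.
#' @param pi_value Value of pi used in the area formula; default full
#'   precision, set to 3.14 for compatibility with the printed coverage
#'   areas.
#' @return An object of class `electrode_geometry`.
#' @export
electrode_geometry <- function(ring_dim_mm, width_mm = 12.6, pi_value = pi) {
  if (ring_dim_mm < 10 || ring_dim_mm > 40) {
    stop("ring_dim_mm must lie in [10, 40] mm (adjustable probe range)",
         call. = FALSE)
  }
  if (width_mm < 0) stop("width_mm must be >= 0", call. = FALSE)
  structure(list(ring_dim_mm = ring_dim_mm, width_mm = width_mm,
                 pi_value = pi_value),
            class = "electrode_geometry")
}

#' Electrode surface coverage area
#'
#' `S = 2 * pi * R * h` with the printed ring dimension plugged directly in
#' as R (the convention that reproduces the published coverage areas;
#' with `pi_value = 3.14`, 10 mm gives 791.28 mm^2 and 40 mm gives
#' 3165.12 mm^2).
#'
#' @param geom An [electrode_geometry()].
#' @return Coverage area (mm^2).
#' @export
coverage_area <- function(geom) {
  stopifnot(inherits(geom, "electrode_geometry"))
  2 * geom$pi_value * geom$ring_dim_mm * geom$width_mm
}

#' Full characterization report
#'
#' Bundles the static-characterization chain for a sensor spec: sensitivity
#' factor, resolution, accuracy, environmental error bounds and a coverage
#' area table over the adjustable electrode range.
#'
#' @param spec A [sensor_spec()].
#' @param full_range_error_pct Full-range measurement error (%); default
#'   3.52.
#' @param v_low,v_high Environmental voltage fluctuation bounds (V); defaults
#'   0.005 and 0.025.
#' @param diameters_mm Ring dimensions for the coverage table (mm); default
#'   seq(10, 40, by = 5).
#' @param width_mm Electrode width (mm); default 12.6.
#' @param pi_value pi used for coverage areas; default 3.14 (printed-value
#'   compatibility).
#' @return A list of class `characterization_report`.
#' @export
characterization_report <- function(spec = sensor_spec(),
                                    full_range_error_pct = 3.52,
                                    v_low = 0.005, v_high = 0.025,
                                    diameters_mm = seq(10, 40, by = 5),
                                    width_mm = 12.6, pi_value = 3.14) {
  sf <- sensitivity_factor(spec)
  env <- env_error_bounds(v_low, v_high, spec)
  areas <- vapply(diameters_mm, function(d) {
    coverage_area(electrode_geometry(d, width_mm, pi_value))
  }, numeric(1))
  structure(list(
    sensitivity_pct_per_v = sf$rounded,
    sensitivity_pct_per_v_raw = sf$raw,
    resolution_pct = resolution(spec),
    accuracy_pm_pct = accuracy_pm(full_range_error_pct),
    env_error = list(low_pct = env$low_pct, high_pct = env$high_pct,
                     halfwidth_pct = env$halfwidth_pct),
    coverage_mm2 = data.frame(ring_dim_mm = diameters_mm, area_mm2 = areas),
    spec = unclass(spec)
  ), class = "characterization_report")
}

#' @export
print.characterization_report <- function(x, ...) {
  cat("Sensor characterization\n")
  cat(sprintf("  Sensitivity factor: %.2f %%/V (raw %.6f)\n",
              x$sensitivity_pct_per_v, x$sensitivity_pct_per_v_raw))
  cat(sprintf("  Resolution:         %.2f %%\n", x$resolution_pct))
  cat(sprintf("  Accuracy:           +/-%.2f %%\n", x$accuracy_pm_pct))
  cat(sprintf("  Env. error bounds:  %.2f%% to %.2f%% (+/-%.3f%%)\n",
              x$env_error$low_pct, x$env_error$high_pct,
              x$env_error$halfwidth_pct))
  cat("  Coverage area (mm^2) by ring dimension (mm):\n")
  for (i in seq_len(nrow(x$coverage_mm2))) {
    cat(sprintf("    %4.0f mm  %10.2f mm^2\n",
                x$coverage_mm2$ring_dim_mm[i], x$coverage_mm2$area_mm2[i]))
  }
  invisible(x)
}
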
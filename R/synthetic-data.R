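# Synthetic-experiment simulator: chamber ramp / diurnal field temperature
# protocols, first-order liquid<->ice phase dynamics with known ground truth,
# and noisy sensor voltages generated through the calibration line or the
# full physics chain.

#' Temperature protocol
#'
#' Either a freeze-thaw chamber staircase (`ramp_cycle`: cool from `start_c`
#' to `min_c` in `step_c` decrements held `step_minutes` each, then warm back
#' symmetrically) or a sinusoidal `diurnal` field cycle.
#'
#' @param kind `"ramp_cycle"` or `"diurnal"`.
#' @param start_c,min_c Ramp start and minimum temperatures (deg C);
#'   `min_c < start_c`.
#' @param step_c Temperature decrement per step (deg C), > 0.
#' @param step_minutes Hold time per step (min), > 0.
#' @param mean_c,amplitude_c,period_hours,duration_days Diurnal sinusoid
#'   parameters.
#' @return An object of class `temperature_protocol`.
#' @export
temperature_protocol <- function(kind = c("ramp_cycle", "diurnal"),
                                 start_c = 20, min_c = -16, step_c = 3,
                                 step_minutes = 10,
                                 mean_c = -5, amplitude_c = 10,
                                 period_hours = 24, duration_days = 3) {
  kind <- match.arg(kind)
  if (step_minutes <= 0) stop("step_minutes must be > 0", call. = FALSE)
  if (kind == "ramp_cycle") {
    if (min_c >= start_c) stop("ramp_cycle requires min_c < start_c",
                               call. = FALSE)
    if (step_c <= 0) stop("step_c must be > 0", call. = FALSE)
  }
  structure(list(kind = kind, start_c = start_c, min_c = min_c,
                 step_c = step_c, step_minutes = step_minutes,
                 mean_c = mean_c, amplitude_c = amplitude_c,
                 period_hours = period_hours, duration_days = duration_days),
            class = "temperature_protocol")
}

#' Chamber freeze-thaw protocols
#'
#' Convenience constructors for the two standard freeze-thaw chamber runs:
#' chamber A cools a simulated branch from 20 to -16 deg C and back at
#' 3 deg C every 10 min; chamber B cools a live branch from 20 to -20 deg C
#' and back at 2 deg C every 10 min.
#'
#' @return A `ramp_cycle` [temperature_protocol()].
#' @export
chamber_a_protocol <- function() {
  temperature_protocol("ramp_cycle", start_c = 20, min_c = -16,
                       step_c = 3, step_minutes = 10)
}

#' @rdname chamber_a_protocol
#' @export
chamber_b_protocol <- function() {
  temperature_protocol("ramp_cycle", start_c = 20, min_c = -20,
                       step_c = 2, step_minutes = 10)
}

#' Phase dynamics parameters
#'
#' First-order relaxation of the frozen fraction toward a
#' temperature-dependent equilibrium: 0 above the freezing point,
#' `1 - unfrozen_fraction_min` below it. A fixture generator for testing the
#' pipeline, not a mechanistic freezing model.
#'
#' @param theta_total Total volumetric water content (%), in (0, 100\];
#'   default 45 (the chamber sample's moisture content).
#' @param freeze_point_c Freezing point (deg C), default 0.
#' @param rate_per_min First-order relaxation rate (1/min), > 0; default
#'   0.15 (e-folding ~6.7 min, so the frozen fraction tracks a 10-min
#'   chamber staircase with visible lag).
#' @param unfrozen_fraction_min Residual liquid fraction at deep frost
#'   (bound water that never freezes), in \[0, 1); default 0.1.
#' @param density_ratio rho_ice / rho_water used for the ground-truth ice
#'   content; default 0.917.
#' @return An object of class `phase_dynamics`.
#' @export
phase_dynamics <- function(theta_total = 45, freeze_point_c = 0,
                           rate_per_min = 0.15, unfrozen_fraction_min = 0.1,
                           density_ratio = 0.917) {
  if (theta_total <= 0 || theta_total > 100) {
    stop("theta_total must lie in (0, 100]", call. = FALSE)
  }
  if (rate_per_min <= 0) stop("rate_per_min must be > 0", call. = FALSE)
  if (unfrozen_fraction_min < 0 || unfrozen_fraction_min >= 1) {
    stop("unfrozen_fraction_min must lie in [0, 1)", call. = FALSE)
  }
  if (density_ratio <= 0 || density_ratio > 1) {
    stop("density_ratio must lie in (0, 1]", call. = FALSE)
  }
  structure(list(theta_total = theta_total, freeze_point_c = freeze_point_c,
                 rate_per_min = rate_per_min,
                 unfrozen_fraction_min = unfrozen_fraction_min,
                 density_ratio = density_ratio),
            class = "phase_dynamics")
}

#' Simulation configuration
#'
#' @param protocol A [temperature_protocol()].
#' @param dynamics A [phase_dynamics()].
#' @param noise_sd_v Gaussian voltage noise sd (V), >= 0; default 0.002
#'   (about 2.5 ADC steps of 0.0008 V).
#' @param sample_minutes Sampling cadence (min); default 1 (indoor chamber
#'   cadence; field deployments log every 10 min).
#' @param seed Integer RNG seed; a fixed seed makes the simulated series
#'   byte-identical across runs.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(protocol = chamber_a_protocol(),
                              dynamics = phase_dynamics(),
                              noise_sd_v = 0.002, sample_minutes = 1,
                              seed = 1L) {
  stopifnot(inherits(protocol, "temperature_protocol"),
            inherits(dynamics, "phase_dynamics"))
  if (noise_sd_v < 0) stop("noise_sd_v must be >= 0", call. = FALSE)
  if (sample_minutes <= 0) stop("sample_minutes must be > 0", call. = FALSE)
  structure(list(protocol = protocol, dynamics = dynamics,
                 noise_sd_v = noise_sd_v, sample_minutes = sample_minutes,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Generate a temperature series from a protocol
#'
#' `ramp_cycle` yields a piecewise-constant staircase down to `min_c` then
#' symmetrically back up; `diurnal` a sinusoid sampled at the cadence.
#'
#' @param protocol A [temperature_protocol()].
#' @param sample_minutes Sampling cadence (min).
#' @return data.frame with columns `minutes` (from start) and `temp_c`.
#' @export
make_temperature_series <- function(protocol, sample_minutes = 1) {
  stopifnot(inherits(protocol, "temperature_protocol"))
  if (sample_minutes <= 0) stop("sample_minutes must be > 0", call. = FALSE)
  if (protocol$kind == "ramp_cycle") {
    n_down <- ceiling((protocol$start_c - protocol$min_c) / protocol$step_c)
    total_min <- 2 * n_down * protocol$step_minutes
    minutes <- seq(0, total_min, by = sample_minutes)
    level <- floor(minutes / protocol$step_minutes)
    temp <- ifelse(
      level <= n_down,
      pmax(protocol$start_c - protocol$step_c * level, protocol$min_c),
      pmin(protocol$min_c + protocol$step_c * (level - n_down),
           protocol$start_c)
    )
  } else {
    total_min <- protocol$duration_days * 24 * 60
    minutes <- seq(0, total_min, by = sample_minutes)
    temp <- protocol$mean_c +
      protocol$amplitude_c * sin(2 * pi * minutes /
                                   (protocol$period_hours * 60))
  }
  data.frame(minutes = minutes, temp_c = temp)
}

#' Simulate liquid/ice phase dynamics along a temperature series
#'
#' The frozen fraction starts at 0 (unfrozen branch) and relaxes toward its
#' temperature-dependent equilibrium with per-step gain
#' `1 - exp(-rate_per_min * dt)`. Ground truth satisfies mass conservation at
#' every sample: `theta_liquid + delta_true / density_ratio = theta_total`.
#'
#' @param temp_c Numeric temperature series (deg C).
#' @param dynamics A [phase_dynamics()].
#' @param sample_minutes Sampling interval between consecutive temperatures
#'   (min).
#' @return data.frame with columns `theta_liquid` (%) and `delta_true` (%).
#' @export
simulate_phase <- function(temp_c, dynamics, sample_minutes = 1) {
  stopifnot(inherits(dynamics, "phase_dynamics"))
  n <- length(temp_c)
  f_eq <- ifelse(temp_c <= dynamics$freeze_point_c,
                 1 - dynamics$unfrozen_fraction_min, 0)
  gain <- 1 - exp(-dynamics$rate_per_min * sample_minutes)
  f <- numeric(n)
  state <- 0
  for (i in seq_len(n)) {
    state <- state + gain * (f_eq[i] - state)
    f[i] <- state
  }
  theta_liquid <- dynamics$theta_total * (1 - f)
  delta_true <- (dynamics$theta_total - theta_liquid) * dynamics$density_ratio
  data.frame(theta_liquid = theta_liquid, delta_true = delta_true)
}

#' Simulate a full sensor reading series with ground truth
#'
#' Closes the loop from temperature protocol to sensor voltages. By default
#' (`method = "calibration"`) the voltage is the inverse of the calibration
#' line, `U = (theta_liquid - intercept_b) / slope_k`, plus seeded Gaussian
#' noise, so pipeline tests are decoupled from the physics-model mode
#' decisions. `method = "physics"` instead routes the liquid fraction through
#' the dielectric-mixture forward chain
#' ([mixture_impedance()] then [probe_voltage()]).
#'
#' @param config A [simulation_config()].
#' @param calibration A [calibration_model()] (nonzero slope) used to invert
#'   water content into voltage (and to process the output downstream).
#' @param method `"calibration"` (default) or `"physics"`.
#' @param physics A [probe_physics()] for `method = "physics"`; defaults to
#'   [default_probe_physics()].
#' @param r_total_ohm Mixture parallel resistance for the physics route
#'   (Ohm).
#' @param origin Timestamp of the first sample (POSIXct, UTC).
#' @return List with `readings` (data.frame `timestamp`, `voltage_v`,
#'   `temp_c`), `truth` (data.frame `timestamp`, `theta_liquid_pct`,
#'   `delta_true_pct`) and the echoed `config`.
#' @export
simulate_readings <- function(config, calibration,
                              method = c("calibration", "physics"),
                              physics = NULL, r_total_ohm = 10,
                              origin = as.POSIXct("2018-12-01 00:00:00",
                                                  tz = "UTC")) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(calibration, "calibration_model"))
  method <- match.arg(method)
  if (calibration$slope_k == 0) stop("calibration slope must be nonzero",
                                     call. = FALSE)
  temps <- make_temperature_series(config$protocol, config$sample_minutes)
  phase <- simulate_phase(temps$temp_c, config$dynamics,
                          config$sample_minutes)
  if (method == "calibration") {
    u_clean <- (phase$theta_liquid - calibration$intercept_b) /
      calibration$slope_k
  } else {
    if (is.null(physics)) physics <- default_probe_physics()
    u_clean <- vapply(phase$theta_liquid / 100, function(frac) {
      comp <- phase_composition(V = 1, Vl = frac, eps_l = physics$eps_l)
      probe_voltage(mixture_impedance(comp, r_total_ohm, physics,
                                      mode = "simplified"), physics)
    }, numeric(1))
  }
  set.seed(config$seed)
  noise <- stats::rnorm(length(u_clean), mean = 0, sd = config$noise_sd_v)
  timestamp <- origin + temps$minutes * 60
  list(
    readings = data.frame(timestamp = timestamp,
                          voltage_v = u_clean + noise,
                          temp_c = temps$temp_c),
    truth = data.frame(timestamp = timestamp,
                       theta_liquid_pct = phase$theta_liquid,
                       delta_true_pct = phase$delta_true),
    config = config
  )
}
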
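# Deployed freeze-thaw pipeline: frozen-state detection from ambient
# temperature, pre-freeze water-content baseline, volumetric ice content
# delta = (theta0 - theta_x) * rho_ice/rho_water, ice freeze-thaw rate
# sigma = |d delta| / |dt|, and rate summary statistics.

#' Pipeline configuration
#'
#' @param freezing_point Freezing threshold (deg C); a sample is flagged
#'   frozen when ambient temperature is less than or equal to it (inclusive
#'   boundary). Default 0.
#' @param density_ratio rho_ice / rho_water (dimensionless), in (0, 1\];
#'   default 0.917 (917 / 1000 kg m^-3).
#' @param baseline_window Number of pre-freeze samples averaged to establish
#'   the baseline water content theta0; default 3 (suppresses single-sample
#'   noise).
#' @param clamp_negative_ice Clamp negative raw ice contents (sensor noise
#'   pushing theta_x above theta0) to 0; default TRUE. Clamp events are
#'   counted in the output's `n_clamped` attribute.
#' @param thaw_end_tol Ice content (%) below which a thawing branch is
#'   declared fully melted, ending the freeze episode; default 0.05, the
#'   sensor resolution.
#' @param rate_time_unit Time unit of the freeze-thaw rate; fixed to
#'   `"min"` (%/min).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(freezing_point = 0, density_ratio = 0.917,
                            baseline_window = 3, clamp_negative_ice = TRUE,
                            thaw_end_tol = 0.05, rate_time_unit = "min") {
  if (density_ratio <= 0 || density_ratio > 1) {
    stop("density_ratio must lie in (0, 1]", call. = FALSE)
  }
  if (baseline_window < 1) stop("baseline_window must be >= 1", call. = FALSE)
  if (thaw_end_tol < 0) stop("thaw_end_tol must be >= 0", call. = FALSE)
  rate_time_unit <- match.arg(rate_time_unit, "min")
  structure(list(freezing_point = freezing_point,
                 density_ratio = density_ratio,
                 baseline_window = as.integer(baseline_window),
                 clamp_negative_ice = isTRUE(clamp_negative_ice),
                 thaw_end_tol = thaw_end_tol,
                 rate_time_unit = rate_time_unit),
            class = "pipeline_config")
}

#' Frozen-state detection from ambient temperature
#'
#' A branch is considered frozen when the ambient temperature reaches the
#' freezing point: `temp <= freezing_point`, boundary included.
#'
#' @param temps Numeric vector of ambient temperatures (deg C).
#' @param freezing_point Threshold (deg C), default 0.
#' @return Logical vector, same length as `temps`.
#' @export
detect_frozen <- function(temps, freezing_point = 0) {
  temps <= freezing_point
}

check_series <- function(series) {
  if (!is.data.frame(series) ||
      !all(c("timestamp", "voltage_v", "temp_c") %in% names(series))) {
    stop("sensor series must be a data.frame with columns ",
         "'timestamp', 'voltage_v', 'temp_c'", call. = FALSE)
  }
  ts <- as.numeric(series$timestamp)
  if (nrow(series) > 1 && any(diff(ts) <= 0)) {
    i <- which(diff(ts) <= 0)[1] + 1L
    stop("timestamps must be strictly increasing (violated at row ", i, ")",
         call. = FALSE)
  }
  invisible(series)
}

#' Pre-freeze baseline water content theta0
#'
#' Mean calibrated water content over the last `baseline_window` samples
#' strictly before the first frozen sample. If the series never freezes the
#' trailing window of the whole series is used (theta0 is then unused by the
#' pipeline but still well defined).
#'
#' @param series data.frame with columns `timestamp`, `voltage_v`, `temp_c`,
#'   timestamps strictly increasing.
#' @param model A [calibration_model()].
#' @param config A [pipeline_config()].
#' @return Baseline volumetric water content theta0 (%).
#' @export
baseline_theta0 <- function(series, model, config = pipeline_config()) {
  check_series(series)
  frozen <- detect_frozen(series$temp_c, config$freezing_point)
  first <- if (any(frozen)) which(frozen)[1] else nrow(series) + 1L
  if (first == 1L) {
    stop("missing baseline: series is frozen from the first sample; ",
         "supply theta0 explicitly", call. = FALSE)
  }
  idx <- seq.int(max(1L, first - config$baseline_window), first - 1L)
  mean(apply_calibration(series$voltage_v[idx], model))
}

#' Volumetric ice content from the water-content drop
#'
#' `delta = (theta0 - theta_x) * density_ratio`: the liquid water lost since
#' the pre-freeze baseline, converted to an ice volume via the ice/water
#' density ratio.
#'
#' @param theta0 Baseline water content (%), in \[0, 100\].
#' @param theta_x Instantaneous water content (%), in \[0, 100\]; vectorised.
#' @param density_ratio rho_ice / rho_water, default 0.917.
#' @param clamp_negative Clamp negative raw values to 0 (default TRUE); the
#'   number of clamped elements is attached as attribute `n_clamped`.
#' @return Ice content delta (%), with attribute `n_clamped`.
#' @export
ice_content <- function(theta0, theta_x, density_ratio = 0.917,
                        clamp_negative = TRUE) {
  if (any(c(theta0, theta_x) < 0) || any(c(theta0, theta_x) > 100)) {
    stop("theta0 and theta_x must lie in [0, 100]", call. = FALSE)
  }
  raw <- (theta0 - theta_x) * density_ratio
  delta <- if (clamp_negative) pmax(raw, 0) else raw
  attr(delta, "n_clamped") <- if (clamp_negative) sum(raw < 0) else 0L
  delta
}

#' Ice freeze-thaw rate by forward differencing
#'
#' `sigma(t) = |delta(t') - delta(t)| / |t' - t|` where `t'` is the adjacent
#' later sample; expressed in %/min. The last sample has no later neighbour
#' and is assigned 0 by convention. The absolute value makes sigma
#' nonnegative and invariant under time reversal of the ice series.
#'
#' @param timestamps POSIXct vector or numeric seconds; strictly increasing.
#' @param delta Ice content series (%), same length.
#' @return sigma (%/min), same length as `delta`.
#' @export
freeze_thaw_rate <- function(timestamps, delta) {
  ts <- as.numeric(timestamps)
  if (length(ts) != length(delta)) {
    stop("timestamps and delta must have equal length", call. = FALSE)
  }
  if (length(ts) >= 2) {
    dt <- diff(ts)
    if (any(dt == 0)) {
      stop("duplicate timestamps at position ", which(dt == 0)[1] + 1L,
           call. = FALSE)
    }
    if (any(dt < 0)) {
      stop("timestamps must be strictly increasing", call. = FALSE)
    }
    sigma <- c(abs(diff(delta)) / (dt / 60), 0)
  } else {
    sigma <- rep(0, length(delta))
  }
  sigma
}

#' Process a sensor time series into freeze-thaw records
#'
#' The deployed pipeline: calibrate voltages to water content, flag frozen
#' samples from ambient temperature, establish the pre-freeze baseline
#' theta0, and compute per-sample ice content and freeze-thaw rate.
#'
#' Ice content is tracked per *freeze episode*: an episode opens at a
#' frozen-flag onset (with theta0 taken from the `baseline_window` samples
#' before the onset, or from `theta0` if supplied for a series that starts
#' frozen) and remains open through the subsequent thaw until the raw ice
#' content decays below `thaw_end_tol`, because ice persists after the
#' ambient temperature rises back above the freezing point. Outside episodes
#' delta is 0. Each new onset after a completed episode re-establishes the
#' baseline.
#'
#' @param series data.frame with columns `timestamp`, `voltage_v`, `temp_c`,
#'   strictly increasing timestamps.
#' @param model A [calibration_model()].
#' @param config A [pipeline_config()].
#' @param theta0 Optional explicit baseline (%) used for the first episode
#'   when no pre-freeze samples exist.
#' @return data.frame with columns `timestamp`, `theta_pct`, `delta_pct`,
#'   `sigma_pct_per_min`, `frozen`; attributes `baselines` (data.frame of
#'   episode start index and theta0) and `n_clamped`.
#' @export
process_series <- function(series, model, config = pipeline_config(),
                           theta0 = NULL) {
  check_series(series)
  stopifnot(inherits(model, "calibration_model"),
            inherits(config, "pipeline_config"))
  n <- nrow(series)
  frozen <- detect_frozen(series$temp_c, config$freezing_point)
  theta_x <- as.numeric(apply_calibration(series$voltage_v, model))

  delta <- numeric(n)
  n_clamped <- 0L
  in_episode <- FALSE
  th0 <- NA_real_
  ep_start <- integer(0)
  ep_theta0 <- numeric(0)

  for (i in seq_len(n)) {
    if (!in_episode && frozen[i]) {
      if (i == 1L) {
        if (is.null(theta0)) {
          stop("missing baseline: series is frozen from the first sample; ",
               "supply theta0 explicitly", call. = FALSE)
        }
        th0 <- theta0
      } else {
        idx <- seq.int(max(1L, i - config$baseline_window), i - 1L)
        th0 <- mean(theta_x[idx])
      }
      in_episode <- TRUE
      ep_start <- c(ep_start, i)
      ep_theta0 <- c(ep_theta0, th0)
    }
    if (in_episode) {
      raw <- (th0 - theta_x[i]) * config$density_ratio
      if (config$clamp_negative_ice && raw < 0) {
        delta[i] <- 0
        n_clamped <- n_clamped + 1L
      } else {
        delta[i] <- raw
      }
      if (!frozen[i] && raw < config$thaw_end_tol) in_episode <- FALSE
    } else {
      delta[i] <- 0
    }
  }

  out <- data.frame(timestamp = series$timestamp,
                    theta_pct = theta_x,
                    delta_pct = delta,
                    sigma_pct_per_min = freeze_thaw_rate(series$timestamp,
                                                         delta),
                    frozen = frozen)
  attr(out, "baselines") <- data.frame(start_index = ep_start,
                                       theta0 = ep_theta0)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Summary statistics of the ice freeze-thaw rate
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum and maximum
#' of the freeze-thaw rate series, the four columns of the overwintering
#' volatility summary.
#'
#' @param records Output of [process_series()], or a numeric sigma vector.
#' @return Named list `mean`, `sd`, `min`, `max` (class `rate_summary`).
#' @export
summarize_rates <- function(records) {
  sigma <- if (is.data.frame(records)) {
    if (!"sigma_pct_per_min" %in% names(records)) {
      stop("records must contain a 'sigma_pct_per_min' column", call. = FALSE)
    }
    records$sigma_pct_per_min
  } else {
    as.numeric(records)
  }
  if (length(sigma) < 2) {
    stop("insufficient data: need >= 2 records to summarise rates",
         call. = FALSE)
  }
  structure(list(mean = mean(sigma), sd = stats::sd(sigma),
                 min = min(sigma), max = max(sigma)),
            class = "rate_summary")
}

#' @export
print.rate_summary <- function(x, ...) {
  cat("Ice freeze-thaw rate (%/min)\n")
  cat(sprintf("  Mean Value:         %.5f\n", x$mean))
  cat(sprintf("  Standard Deviation: %.5f\n", x$sd))
  cat(sprintf("  Minimum Value:      %.5f\n", x$min))
  cat(sprintf("  Maximum Value:      %.5f\n", x$max))
  invisible(x)
}
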
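# Shared fixtures: the three published per-species calibration models and
# small series builders. Everything is generated in code; no data files.

table2_models <- list(
  juniperus = calibration_model(31.28, -6.13, 0.9845,
                                species = "Juniperus virginiana"),
  lagerstroemia = calibration_model(52.27, -30.97, 0.9803,
                                    species = "Lagerstroemia indica"),
  pachira = calibration_model(49.11, -12.63, 0.9892,
                              species = "Pachira glabra")
)

# exact pairs on a model's line over a voltage grid (kept inside the 0-100%
# physical range for all three published models)
pairs_on_line <- function(model, U = seq(0.7, 2.0, length.out = 9)) {
  data.frame(voltage_v = U,
             theta_pct = model$slope_k * U + model$intercept_b)
}

# sensor series at a fixed cadence; voltages chosen to calibrate to theta
series_from_theta <- function(theta, temp_c, model,
                              cadence_min = 1,
                              origin = as.POSIXct("2019-01-01 00:00:00",
                                                  tz = "UTC")) {
  n <- length(theta)
  stopifnot(length(temp_c) == n)
  data.frame(
    timestamp = origin + seq_len(n) * 60 * cadence_min,
    voltage_v = (theta - model$intercept_b) / model$slope_k,
    temp_c = temp_c
  )
}
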
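# Linear voltage -> volumetric water content calibration: fitting, applying,
# and JSON persistence of per-species models (theta = k * U + b).

#' Construct a calibration model
#'
#' A per-species linear map from sensor output voltage to volumetric water
#' content, `theta = slope_k * U + intercept_b`, with the fit's coefficient
#' of determination.
#'
#' @param slope_k Slope (% per V); finite and nonzero.
#' @param intercept_b Intercept (%).
#' @param r_squared Coefficient of determination in \[0, 1\].
#' @param species Free-text label identifying the species / instrument the
#'   model was fitted for.
#' @param fitted_at ISO-8601 timestamp string; defaults to now (UTC).
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(slope_k, intercept_b, r_squared = 1,
                              species = "unspecified",
                              fitted_at = format(Sys.time(),
                                                 "%Y-%m-%dT%H:%M:%SZ",
                                                 tz = "UTC")) {
  if (!is.finite(slope_k) || slope_k == 0) {
    stop("slope_k must be finite and nonzero", call. = FALSE)
  }
  if (!is.finite(intercept_b)) stop("intercept_b must be finite",
                                    call. = FALSE)
  if (!is.finite(r_squared) || r_squared < 0 || r_squared > 1) {
    stop("r_squared must lie in [0, 1] (got ", r_squared, ")", call. = FALSE)
  }
  structure(list(species = as.character(species),
                 slope_k = slope_k,
                 intercept_b = intercept_b,
                 r_squared = r_squared,
                 fitted_at = fitted_at),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration> %s: theta = %.4g * U %+.4g  (R^2 = %.4f)\n",
              x$species, x$slope_k, x$intercept_b, x$r_squared))
  invisible(x)
}

check_pairs <- function(pairs) {
  if (!is.data.frame(pairs) ||
      !all(c("voltage_v", "theta_pct") %in% names(pairs))) {
    stop("calibration pairs must be a data.frame with columns ",
         "'voltage_v' and 'theta_pct'", call. = FALSE)
  }
  if (any(pairs$theta_pct < 0 | pairs$theta_pct > 100)) {
    stop("theta_pct must lie in [0, 100]", call. = FALSE)
  }
  if (any(pairs$voltage_v < 0)) {
    stop("voltage_v must be >= 0", call. = FALSE)
  }
  pairs
}

#' Fit a voltage-to-water-content calibration
#'
#' Ordinary least squares of volumetric water content (ground truth from the
#' gravimetric drying method) on sensor output voltage, the direction in
#' which the model is deployed. Noiseless linear data are recovered exactly
#' (R^2 = 1); drying-method calibrations typically reach R^2 >= 0.98.
#'
#' @param pairs data.frame with columns `voltage_v` (V, >= 0) and `theta_pct`
#'   (%, in \[0, 100\]); at least 3 rows with non-constant voltage.
#' @param species Label stored on the model.
#' @return A [calibration_model()].
#' @examples
#' pairs <- data.frame(voltage_v = 1:5 / 2,
#'                     theta_pct = 31.28 * (1:5 / 2) - 6.13)
#' fit_calibration(pairs, species = "Juniperus virginiana")
#' @export
fit_calibration <- function(pairs, species = "unspecified") {
  check_pairs(pairs)
  if (nrow(pairs) < 3) {
    stop("insufficient data: need >= 3 calibration pairs, got ", nrow(pairs),
         call. = FALSE)
  }
  if (stats::var(pairs$voltage_v) == 0) {
    stop("insufficient data: calibration voltages have zero variance",
         call. = FALSE)
  }
  fit <- stats::lm(theta_pct ~ voltage_v, data = pairs)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  # R^2 against the mean; defined as 1 for an exactly constant response
  tss <- sum((pairs$theta_pct - mean(pairs$theta_pct))^2)
  r2 <- if (tss == 0) 1 else 1 - sum(stats::resid(fit)^2) / tss
  r2 <- min(max(r2, 0), 1)
  if (abs(slope) < sqrt(.Machine$double.eps)) {
    warning("fitted slope is (near) zero: voltage carries no information ",
            "about water content for these pairs", call. = FALSE)
    slope <- if (slope == 0) .Machine$double.eps else slope
  }
  calibration_model(slope_k = slope, intercept_b = intercept,
                    r_squared = r2, species = species)
}

#' Apply a calibration model to sensor voltages
#'
#' Computes `theta = slope_k * U + intercept_b` and clamps the result to the
#' physical range \[0, 100\] %. Clamping (rather than erroring) tolerates the
#' small voltage drift outside the calibrated span that field deployments
#' show; the raw values and a per-element clamp flag are attached as
#' attributes `"raw"` and `"clamped"` for auditing.
#'
#' @param U Numeric vector of sensor voltages (V).
#' @param model A [calibration_model()].
#' @return Numeric vector of volumetric water content (%), clamped, with
#'   attributes `raw` and `clamped`.
#' @export
apply_calibration <- function(U, model) {
  stopifnot(inherits(model, "calibration_model"))
  raw <- model$slope_k * U + model$intercept_b
  theta <- pmin(pmax(raw, 0), 100)
  attr(theta, "raw") <- raw
  attr(theta, "clamped") <- raw < 0 | raw > 100
  theta
}

#' Save / load a calibration model as JSON
#'
#' `save_calibration()` writes all model fields to a JSON file;
#' `load_calibration()` reads it back, validating that every field is present
#' and within its invariants, so that the round trip preserves values exactly
#' for decimal-representable numbers.
#'
#' @param model A [calibration_model()].
#' @param path File path for the JSON calibration file.
#' @return `save_calibration()` returns `path` invisibly;
#'   `load_calibration()` returns a [calibration_model()].
#' @export
save_calibration <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_calibration
#' @export
load_calibration <- function(path) {
  if (!file.exists(path)) {
    stop("calibration file not found: ", path, call. = FALSE)
  }
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("cannot parse calibration file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  required <- c("species", "slope_k", "intercept_b", "r_squared")
  missing <- setdiff(required, names(obj))
  if (length(missing) > 0) {
    stop("calibration file '", path, "' is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (f in c("slope_k", "intercept_b", "r_squared")) {
    if (!is.numeric(obj[[f]]) || length(obj[[f]]) != 1) {
      stop("calibration field '", f, "' must be a single number",
           call. = FALSE)
    }
  }
  calibration_model(slope_k = obj$slope_k, intercept_b = obj$intercept_b,
                    r_squared = obj$r_squared, species = obj$species,
                    fitted_at = if (is.null(obj$fitted_at)) NA_character_
                                else obj$fitted_at)
}

#' Read calibration pairs from CSV
#'
#' Expects columns `voltage_v` and `theta_pct` (comma-delimited, header row,
#' `.` decimal separator).
#'
#' @param path CSV file path.
#' @return data.frame of validated calibration pairs.
#' @export
read_calibration_csv <- function(path) {
  if (!file.exists(path)) {
    stop("calibration pairs file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_pairs(df)
}
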
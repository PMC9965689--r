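# CSV/JSON readers and writers with a fixed dialect: comma delimiter, header
# row, "." decimal separator, UTF-8, ISO-8601 UTC timestamps.

parse_iso8601 <- function(x, what = "timestamp") {
  ts <- as.POSIXct(sub("Z$", "", x), tz = "UTC",
                   format = "%Y-%m-%dT%H:%M:%S")
  # fall back to a space-separated variant before declaring a row bad
  bad <- is.na(ts)
  if (any(bad)) {
    ts[bad] <- as.POSIXct(x[bad], tz = "UTC",
                          format = "%Y-%m-%d %H:%M:%S")
  }
  if (anyNA(ts)) {
    stop("unparseable ", what, " at row ", which(is.na(ts))[1],
         ": '", x[which(is.na(ts))[1]], "'", call. = FALSE)
  }
  ts
}

format_iso8601 <- function(ts) {
  format(ts, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

#' Read a sensor reading series from CSV
#'
#' Expects exactly the columns `timestamp` (ISO-8601 UTC), `voltage_v` and
#' `temp_c`. Rows are sorted by timestamp (with a warning if the file was out
#' of order); duplicate timestamps are an error naming the offending row.
#'
#' @param path CSV file path.
#' @return data.frame with columns `timestamp` (POSIXct UTC), `voltage_v`,
#'   `temp_c`, strictly increasing timestamps.
#' @export
read_readings_csv <- function(path) {
  if (!file.exists(path)) {
    stop("readings file not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "voltage_v", "temp_c")
  if (!all(need %in% names(df))) {
    stop("readings CSV must have header columns ",
         paste(need, collapse = ", "), " (got: ",
         paste(names(df), collapse = ", "), ")", call. = FALSE)
  }
  ts <- parse_iso8601(df$timestamp)
  for (col in c("voltage_v", "temp_c")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      stop("unparseable ", col, " at row ", which(is.na(v))[1], call. = FALSE)
    }
    df[[col]] <- v
  }
  df$timestamp <- ts
  dup <- duplicated(as.numeric(ts))
  if (any(dup)) {
    stop("duplicate timestamp at row ", which(dup)[1], ": '",
         format_iso8601(ts[which(dup)[1]]), "'", call. = FALSE)
  }
  if (is.unsorted(as.numeric(ts), strictly = TRUE)) {
    warning("readings were out of order; sorted by timestamp",
            call. = FALSE)
    df <- df[order(df$timestamp), , drop = FALSE]
    rownames(df) <- NULL
  }
  df[, need]
}

#' Write a sensor reading series to CSV
#'
#' @param readings data.frame with columns `timestamp`, `voltage_v`,
#'   `temp_c`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_readings_csv <- function(readings, path) {
  out <- data.frame(timestamp = format_iso8601(readings$timestamp),
                    voltage_v = sprintf("%.6f", readings$voltage_v),
                    temp_c = sprintf("%.6f", readings$temp_c))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read freeze-thaw records as CSV
#'
#' Numeric columns are written with 6 decimals, so a write-read round trip
#' is exact to that precision.
#'
#' @param records Output of [process_series()].
#' @param path CSV path.
#' @return `write_records_csv()` returns `path` invisibly;
#'   `read_records_csv()` returns the records data.frame.
#' @export
write_records_csv <- function(records, path) {
  out <- data.frame(
    timestamp = format_iso8601(records$timestamp),
    theta_pct = sprintf("%.6f", records$theta_pct),
    delta_pct = sprintf("%.6f", records$delta_pct),
    sigma_pct_per_min = sprintf("%.6f", records$sigma_pct_per_min),
    frozen = records$frozen
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "theta_pct", "delta_pct", "sigma_pct_per_min",
            "frozen")
  if (!all(need %in% names(df))) {
    stop("records CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$timestamp <- parse_iso8601(df$timestamp)
  df$frozen <- as.logical(df$frozen)
  df
}

#' Write a rate summary as JSON
#'
#' Emits the four overwintering-volatility columns as keys `mean`, `sd`,
#' `min`, `max` together with their human-readable labels.
#'
#' @param summary A `rate_summary` from [summarize_rates()].
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(summary, path) {
  stopifnot(inherits(summary, "rate_summary"))
  obj <- list(mean = summary$mean, sd = summary$sd,
              min = summary$min, max = summary$max,
              labels = list(mean = "Mean Value",
                            sd = "Standard Deviation",
                            min = "Minimum Value",
                            max = "Maximum Value"),
              unit = "%/min")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
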
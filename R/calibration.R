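#' Fit a linear raw-to-kPa conversion for one sensor
#'
#' Ordinary least squares of the applied pressure on the raw digital
#' reading — the direction the acquisition software needs, since it must
#' convert readings into pressure. Hysteresis is summarized as the largest
#' absolute gap, on the calibrated (kPa) scale, between the mean ascending
#' and mean descending reading at the same applied pressure.
#'
#' @param records data.frame with columns `applied_kPa`, `raw_reading` and
#'   optionally `direction` (`"ascending"`/`"descending"`) for the
#'   hysteresis summary. All rows must belong to one sensor.
#' @param sensor_id Identifier stored on the result (defaults to a
#'   `sensor_id` column when present).
#' @return Object of class `sensor_calibration`: `sensor_id`, `slope` (kPa
#'   per raw unit), `intercept` (kPa), `r_squared`, `hysteresis` (kPa,
#'   `NA` when no direction information).
#' @examples
#' rec <- generate_calibration_dataset(1, true_gains = 2, true_offsets = 5)
#' cal <- fit_sensor_calibration(rec)
#' c(cal$slope, cal$intercept)  # 0.5, -2.5
#' @export
fit_sensor_calibration <- function(records, sensor_id = NULL) {
  stopifnot(is.data.frame(records),
            all(c("applied_kPa", "raw_reading") %in% names(records)))
  if (is.null(sensor_id))
    sensor_id <- if ("sensor_id" %in% names(records))
      records$sensor_id[1] else NA
  if (length(unique(records$applied_kPa)) < 2)
    stop("need at least 2 distinct applied pressures")
  if (length(unique(records$raw_reading)) < 2)
    stop("degenerate sensor: all raw readings identical")
  fit <- stats::lm(applied_kPa ~ raw_reading, data = records)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  tss <- sum((records$applied_kPa - mean(records$applied_kPa))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / tss

  hyst <- NA_real_
  if ("direction" %in% names(records) &&
      all(c("ascending", "descending") %in% records$direction)) {
    m <- stats::aggregate(raw_reading ~ applied_kPa + direction,
                          data = records, FUN = mean)
    asc <- m[m$direction == "ascending", ]
    des <- m[m$direction == "descending", ]
    shared <- intersect(asc$applied_kPa, des$applied_kPa)
    if (length(shared)) {
      gaps <- vapply(shared, function(p) {
        abs(asc$raw_reading[asc$applied_kPa == p] -
              des$raw_reading[des$applied_kPa == p])
      }, numeric(1))
      hyst <- abs(slope) * max(gaps)
    }
  }
  structure(list(sensor_id = sensor_id, slope = slope,
                 intercept = intercept, r_squared = r2, hysteresis = hyst),
            class = "sensor_calibration")
}

#' Fit calibrations for every sensor in a calibration table
#'
#' @param records Calibration table (schema of
#'   [generate_calibration_dataset()]).
#' @return Named list of [fit_sensor_calibration()] results keyed by
#'   sensor id.
#' @export
fit_all_calibrations <- function(records) {
  stopifnot("sensor_id" %in% names(records))
  ids <- unique(records$sensor_id)
  out <- lapply(ids, function(s)
    fit_sensor_calibration(records[records$sensor_id == s, , drop = FALSE]))
  names(out) <- as.character(ids)
  out
}

#' Convert raw readings to kPa with a fitted calibration
#'
#' @param raw_series Numeric vector of raw readings (may be empty).
#' @param cal A `sensor_calibration`.
#' @return Pressures in kPa, same length and order.
#' @export
apply_calibration <- function(raw_series, cal) {
  stopifnot(inherits(cal, "sensor_calibration"), is.numeric(raw_series))
  cal$slope * raw_series + cal$intercept
}

#' Leak test on a pressurized bottle
#'
#' A capped bottle is pressurized and monitored; the test fails if the
#' pressure drops by more than the tolerance below the initial reading
#' within the observation window (default 16 h, an overnight watch).
#'
#' @param times Hours since pressurization, increasing.
#' @param pressures Readings in kPa.
#' @param window_h Observation window (h).
#' @param drop_tolerance_kPa Maximum acceptable drop (kPa).
#' @return List `pass` (logical), `max_drop` (kPa).
#' @export
leak_test <- function(times, pressures, window_h = 16,
                      drop_tolerance_kPa = 1) {
  stopifnot(length(times) == length(pressures))
  if (length(times) == 0) stop("empty pressure series")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  keep <- times <= times[1] + window_h
  p <- pressures[keep]
  if (length(p) < 2) {
    warning("single reading in window: no drop observable")
    return(list(pass = TRUE, max_drop = 0))
  }
  max_drop <- p[1] - min(p)
  list(pass = max_drop <= drop_tolerance_kPa, max_drop = max_drop)
}

#' Sensor response check against an ideal-gas expectation
#'
#' A known volume of air injected into a bottle of known head space raises
#' the over-pressure by `p_atm * injected / headspace` (isothermal ideal
#' gas). The calibrated reading is compared to this expectation and drift
#' is flagged beyond the sensor's stated 2.5 percent relative accuracy.
#'
#' @param cal A `sensor_calibration`.
#' @param known_headspace_mL Head-space volume (mL), `> 0`.
#' @param injected_air_mL Injected air (mL), `> 0`.
#' @param raw_reading The sensor's raw reading after injection.
#' @param p_atm Atmospheric pressure (kPa).
#' @param drift_threshold Relative error beyond which drift is flagged.
#' @return List `expected_kPa`, `measured_kPa`, `relative_error`, `drift`.
#' @examples
#' cal <- fit_sensor_calibration(generate_calibration_dataset(1))
#' response_check(cal, 80, 8, raw_reading = 10.1325)$expected_kPa  # 10.1325
#' @export
response_check <- function(cal, known_headspace_mL, injected_air_mL,
                           raw_reading, p_atm = 101.325,
                           drift_threshold = 0.025) {
  if (known_headspace_mL <= 0) stop("head-space volume must be positive")
  if (injected_air_mL <= 0) stop("injected volume must be positive")
  expected <- p_atm * injected_air_mL / known_headspace_mL
  measured <- apply_calibration(raw_reading, cal)
  rel <- (measured - expected) / expected
  list(expected_kPa = expected, measured_kPa = measured,
       relative_error = rel, drift = abs(rel) > drift_threshold)
}
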
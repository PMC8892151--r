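#' Cumulate vent-to-vent pressure readings
#'
#' In a vented protocol each reading is the over-pressure accumulated since
#' the previous vent; the cumulative head-space pressure is their running
#' sum. Small negative readings (sensor noise around zero, down to
#' -0.5 kPa) are clamped to 0 before summing so that noise cannot make the
#' cumulative curve non-monotone; anything below -0.5 kPa is treated as a
#' sensor fault.
#'
#' @param pressures Per-interval over-pressure readings (kPa).
#' @param times Optional reading times (h); must be strictly increasing
#'   when given.
#' @return Cumulative pressure (kPa), same length.
#' @examples
#' cumulate_pressure(c(2, 3, 1.5))    # 2, 5, 6.5
#' cumulate_pressure(c(2, -0.3, 1))   # 2, 2, 3
#' @export
cumulate_pressure <- function(pressures, times = NULL) {
  if (!is.null(times)) {
    stopifnot(length(times) == length(pressures))
    if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  }
  if (any(pressures < -0.5))
    stop("reading below -0.5 kPa: sensor fault")
  cumsum(pmax(pressures, 0))
}

#' Convert cumulative head-space pressure to gas volume
#'
#' Ideal-gas conversion with the bottle's head-space volume `V0`:
#' `gross = (P1 + p_atm) * V0 / p_atm` (the bottle's total gas content
#' referred to ambient pressure, equal to `V0` at zero over-pressure) and
#' `net = P1 * V0 / p_atm = gross - V0` (the evolved gas alone). The net
#' convention is the default: gas production must be 0 at the start of the
#' incubation, and blank subtraction cancels the `V0` offset in any case.
#'
#' @param cumulative_kPa Cumulative over-pressure (kPa), vectorized.
#' @param headspace_volume `V0` in mL, `> 0`.
#' @param p_atm Atmospheric pressure (kPa), `> 0`.
#' @param convention `"net"` (default) or `"gross"`.
#' @return Gas volume in mL.
#' @examples
#' pressure_to_volume(50, 80, 100)                         # 40
#' pressure_to_volume(0, 80, 101.325, convention = "gross") # 80
#' @export
pressure_to_volume <- function(cumulative_kPa, headspace_volume, p_atm,
                               convention = c("net", "gross")) {
  convention <- match.arg(convention)
  if (headspace_volume <= 0) stop("head-space volume must be positive")
  if (p_atm <= 0) stop("atmospheric pressure must be positive")
  net <- cumulative_kPa * headspace_volume / p_atm
  if (convention == "net") net else net + headspace_volume
}

#' Per-gram normalization of gas volumes
#'
#' @param gp_mL Gas volume (mL).
#' @param dm_mass Incubated dry matter (g), `> 0`.
#' @return mL per g incubated DM.
#' @export
normalize_per_dm <- function(gp_mL, dm_mass) {
  if (any(dm_mass <= 0)) stop("dm_mass must be positive")
  gp_mL / dm_mass
}

#' Build the gas-production table from a pressure log
#'
#' Applies (optional) sensor calibration, cumulates the per-interval
#' readings bottle by bottle, converts to volume, and normalizes feed
#' bottles per gram of incubated DM. Blanks keep `gp_mL_per_g = NA`.
#'
#' @param log_table Long pressure log (schema of [pressure_log_table()]).
#' @param design Design table with `bottle_id` and `dm_mass`.
#' @param headspace_volume `V0` (mL) — scalar, or a named vector keyed by
#'   technique when bottles differ between techniques.
#' @param p_atm Atmospheric pressure (kPa).
#' @param convention Volume convention, see [pressure_to_volume()].
#' @param calibrations Optional named list of `sensor_calibration` keyed by
#'   `bottle_id`; readings are converted to kPa before cumulation.
#' @return Long data.frame `run_id`, `technique`, `bottle_id`, `feed_id`,
#'   `replicate`, `time_h`, `cum_pressure_kPa`, `gp_mL`, `gp_mL_per_g`,
#'   `blank_corrected` (FALSE).
#' @export
build_gp_table <- function(log_table, design, headspace_volume,
                           p_atm = 101.325,
                           convention = c("net", "gross"),
                           calibrations = NULL) {
  convention <- match.arg(convention)
  dm <- stats::setNames(design$dm_mass, design$bottle_id)
  ids <- unique(log_table$bottle_id)
  out <- lapply(ids, function(id) {
    d <- log_table[log_table$bottle_id == id, ]
    d <- d[order(d$time_h), ]
    p <- d$pressure_kPa
    if (!is.null(calibrations)) {
      cal <- calibrations[[as.character(id)]]
      if (is.null(cal)) stop("no calibration for bottle ", id)
      p <- apply_calibration(p, cal)
    }
    v0 <- if (length(headspace_volume) > 1)
      headspace_volume[[d$technique[1]]] else headspace_volume
    cum <- cumulate_pressure(p, d$time_h)
    gp <- pressure_to_volume(cum, v0, p_atm, convention)
    m <- dm[[as.character(id)]]
    data.frame(run_id = d$run_id, technique = d$technique, bottle_id = id,
               feed_id = d$feed_id, replicate = d$replicate,
               time_h = d$time_h, cum_pressure_kPa = cum, gp_mL = gp,
               gp_mL_per_g = if (is.na(m)) NA_real_ else gp / m,
               blank_corrected = FALSE)
  })
  do.call(rbind, out)
}

#' Blank-correct one bottle's gas-production series
#'
#' Subtracts, at every time point, the mean gas volume of the blank bottles
#' of the same run. The blank and feed series must share the time grid
#' exactly — no silent interpolation. Corrected values may be negative
#' early in the incubation; they are reported as-is.
#'
#' @param feed_gp data.frame with `time_h` and `gp_mL` for one bottle.
#' @param blank_gps List of data.frames with `time_h` and `gp_mL`, one per
#'   blank bottle of the run.
#' @return `feed_gp` with `gp_mL` corrected and `blank_corrected = TRUE`;
#'   `gp_mL_per_g` is rescaled when a `dm_mass` attribute or column basis
#'   exists (handled by [blank_correct_table()] for whole experiments).
#' @export
blank_correct <- function(feed_gp, blank_gps) {
  if (length(blank_gps) == 0) stop("no blank bottles for this run")
  tgrid <- feed_gp$time_h
  for (b in blank_gps) {
    if (length(b$time_h) != length(tgrid) ||
        any(abs(b$time_h - tgrid) > 1e-9))
      stop("blank and feed series are on different time grids")
  }
  blank_mean <- rowMeans(do.call(cbind, lapply(blank_gps, `[[`, "gp_mL")))
  feed_gp$gp_mL <- feed_gp$gp_mL - blank_mean
  feed_gp$blank_corrected <- TRUE
  feed_gp
}

#' Blank-correct a whole gas-production table
#'
#' Applies [blank_correct()] within each run and technique, using that
#' run's blank bottles, and recomputes `gp_mL_per_g` for feed bottles.
#'
#' @param gp_table Output of [build_gp_table()].
#' @param design Design table with `bottle_id` and `dm_mass`.
#' @return The corrected table (blanks included, also corrected, so that
#'   the corrected blank mean is identically zero).
#' @export
blank_correct_table <- function(gp_table, design) {
  dm <- stats::setNames(design$dm_mass, design$bottle_id)
  groups <- unique(gp_table[, c("run_id", "technique")])
  out <- vector("list", 0)
  for (g in seq_len(nrow(groups))) {
    sub <- gp_table[gp_table$run_id == groups$run_id[g] &
                      gp_table$technique == groups$technique[g], ]
    blank_ids <- unique(sub$bottle_id[sub$feed_id == "blank"])
    if (length(blank_ids) == 0)
      stop("no blank bottles in run ", groups$run_id[g], " (",
           groups$technique[g], ")")
    blanks <- lapply(blank_ids, function(id) {
      b <- sub[sub$bottle_id == id, ]
      b[order(b$time_h), ]
    })
    for (id in unique(sub$bottle_id)) {
      d <- sub[sub$bottle_id == id, ]
      d <- d[order(d$time_h), ]
      d <- blank_correct(d, blanks)
      m <- dm[[as.character(id)]]
      d$gp_mL_per_g <- if (is.na(m)) NA_real_ else d$gp_mL / m
      out[[length(out) + 1L]] <- d
    }
  }
  do.call(rbind, out)
}

#' Interpolate a cumulative gas-production curve
#'
#' Piecewise-linear interpolation on the observed cumulative curve, exact
#' at grid points. Extrapolation outside the observed time range is
#' refused.
#'
#' @param times Observed times (h), increasing.
#' @param values Observed cumulative GP at those times.
#' @param query_times Times to evaluate, all within `[min(times),
#'   max(times)]`.
#' @return Interpolated values at `query_times`.
#' @export
interpolate_gp <- function(times, values, query_times) {
  stopifnot(length(times) == length(values))
  if (any(query_times < min(times) - 1e-9) ||
      any(query_times > max(times) + 1e-9))
    stop("extrapolation outside the observed time range is not supported")
  stats::approx(times, values, xout = query_times, method = "linear",
                ties = "ordered")$y
}
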
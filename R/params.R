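#' Ground-truth fermentation kinetics for one bottle
#'
#' Bundles the true parameters of the exponential-with-lag gas-production
#' model, `G(t) = B (1 - exp(-c (t - L)))` for `t >= L` (0 before the lag),
#' together with the incubated dry-matter mass used to scale per-gram gas
#' volumes to bottle volumes.
#'
#' @param B_true Asymptotic gas production (mL per g incubated DM). Blanks
#'   use `B_true` in absolute mL together with `dm_mass = 1`.
#' @param c_true Fractional rate constant (per hour).
#' @param L_true Lag time (hours).
#' @param dm_mass Incubated dry-matter mass (g); must be positive.
#' @return An object of class `fermentation_params`.
#' @examples
#' fermentation_params(B_true = 200, c_true = 0.08, L_true = 2, dm_mass = 0.2)
#' @export
fermentation_params <- function(B_true, c_true, L_true = 0, dm_mass = 0.2) {
  stopifnot(is.numeric(B_true), is.numeric(c_true), is.numeric(L_true),
            is.numeric(dm_mass), length(B_true) == 1L)
  if (B_true < 0) stop("B_true must be >= 0")
  if (c_true < 0) stop("c_true must be >= 0")
  if (L_true < 0) stop("L_true must be >= 0")
  if (dm_mass <= 0) stop("dm_mass must be > 0")
  structure(list(B_true = B_true, c_true = c_true, L_true = L_true,
                 dm_mass = dm_mass),
            class = "fermentation_params")
}

#' Physical configuration of a fermentation bottle and its sensor
#'
#' Describes the bottle geometry, ambient conditions, the linear response of
#' the pressure sensor mounted on its cap, and the CO2-loss mechanism used by
#' the simulator: gas dissolves into the buffered rumen fluid at a linear
#' equilibrium (`dissolved = solubility_coeff * over-pressure`) and, at each
#' vent event, a fixed fraction of the then-dissolved gas is irreversibly
#' sequestered (lost to bicarbonate buffering and acidification of the
#' medium).
#'
#' @param bottle_volume Total bottle volume (mL).
#' @param fluid_volume Dispensed buffered rumen fluid (mL); must be smaller
#'   than `bottle_volume`.
#' @param p_atm Atmospheric pressure (kPa), read once at the start of a run.
#' @param temperature Incubation temperature (deg C); the simulation is
#'   isothermal and pressure-ratio based, so this is recorded but never
#'   enters the arithmetic.
#' @param sensor_gain,sensor_offset Linear sensor response: a true
#'   over-pressure `P` is recorded as `sensor_gain * P + sensor_offset`
#'   plus Gaussian noise.
#' @param noise_sd Gaussian reading-noise scale, expressed as the SD in kPa
#'   at a 10 kPa reading; the noise SD is proportional to the true reading
#'   (`noise_sd * P / 10`), matching the sensor's stated relative accuracy
#'   of 2.5 percent of the measured value at the default 0.25.
#' @param solubility_coeff mL of gas (at ambient pressure) held in solution
#'   per kPa of head-space over-pressure.
#' @param sequestration_frac Fraction of dissolved gas irreversibly lost at
#'   each vent event; in `[0, 1]`.
#' @return An object of class `apparatus_config` with the derived
#'   `headspace_volume` (mL).
#' @examples
#' apparatus_config()                      # 140-mL bottle, 60 mL fluid
#' apparatus_config(bottle_volume = 60, fluid_volume = 30)  # manual serum bottle
#' @export
apparatus_config <- function(bottle_volume = 140, fluid_volume = 60,
                             p_atm = 101.325, temperature = 39,
                             sensor_gain = 1, sensor_offset = 0,
                             noise_sd = 0.25,
                             solubility_coeff = 0.5,
                             sequestration_frac = 0.3) {
  if (bottle_volume <= 0 || fluid_volume <= 0)
    stop("volumes must be positive")
  if (fluid_volume >= bottle_volume)
    stop("fluid_volume must be smaller than bottle_volume")
  if (p_atm <= 0) stop("p_atm must be positive")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (solubility_coeff < 0) stop("solubility_coeff must be >= 0")
  if (sequestration_frac < 0 || sequestration_frac > 1)
    stop("sequestration_frac must lie in [0, 1]")
  structure(list(bottle_volume = bottle_volume,
                 fluid_volume = fluid_volume,
                 headspace_volume = bottle_volume - fluid_volume,
                 p_atm = p_atm, temperature = temperature,
                 sensor_gain = sensor_gain, sensor_offset = sensor_offset,
                 noise_sd = noise_sd,
                 solubility_coeff = solubility_coeff,
                 sequestration_frac = sequestration_frac),
            class = "apparatus_config")
}

#' Venting and reading schedule for a bottle
#'
#' Three policies are supported. `interval`: read every `interval` hours and
#' vent immediately after every reading (the automated equipment's default,
#' 15-min readings over 48 h giving 192 points). `timepoints`: read and vent
#' at an explicit increasing sequence of hours (the manual technique's
#' 2, 4, 6, 8, 12, 16, 24, 36, 48 h). `threshold`: vent whenever the
#' head-space over-pressure reaches `threshold` kPa, recording a reading at
#' each vent and a final reading at the horizon; this keeps the bottle below
#' the pressure at which CO2 solubility becomes important.
#'
#' @param mode One of `"interval"`, `"timepoints"`, `"threshold"`.
#' @param interval Reading/venting interval (h) for interval mode.
#' @param timepoints Strictly increasing reading times (h) for timepoints
#'   mode; all must lie within the horizon.
#' @param threshold Venting threshold (kPa) for threshold mode.
#' @param horizon Incubation length (h).
#' @return An object of class `venting_schedule`.
#' @examples
#' venting_schedule("interval", interval = 0.25, horizon = 48)
#' venting_schedule("timepoints", timepoints = c(2, 4, 6, 8, 12, 16, 24, 36, 48))
#' venting_schedule("threshold", threshold = 4.5, horizon = 48)
#' @export
venting_schedule <- function(mode = c("interval", "timepoints", "threshold"),
                             interval = 0.25, timepoints = NULL,
                             threshold = 4.5, horizon = 48) {
  mode <- match.arg(mode)
  if (horizon <= 0) stop("horizon must be positive")
  if (mode == "interval") {
    if (!is.numeric(interval) || interval <= 0)
      stop("interval must be a positive number of hours")
  }
  if (mode == "timepoints") {
    if (is.null(timepoints) || length(timepoints) == 0)
      stop("timepoints mode requires a non-empty vector of times")
    if (any(diff(timepoints) <= 0) || timepoints[1] <= 0)
      stop("timepoints must be positive and strictly increasing")
    if (max(timepoints) > horizon)
      stop("timepoints extend beyond the schedule horizon")
  }
  if (mode == "threshold" && (!is.numeric(threshold) || threshold <= 0))
    stop("threshold must be a positive pressure in kPa")
  structure(list(mode = mode, interval = interval, timepoints = timepoints,
                 threshold = threshold, horizon = horizon),
            class = "venting_schedule")
}

#' Reading times implied by a schedule
#'
#' For interval mode the reading times are `interval, 2*interval, ...` up to
#' the horizon — `floor(horizon / interval)` readings. For timepoints mode
#' they are the given times. Threshold mode has no pre-determined reading
#' times (readings occur at vent events), so `NULL` is returned.
#'
#' @param schedule A [venting_schedule()].
#' @return Numeric vector of hours, or `NULL` for threshold mode.
#' @export
reading_times <- function(schedule) {
  stopifnot(inherits(schedule, "venting_schedule"))
  switch(schedule$mode,
         interval = {
           n <- floor(schedule$horizon / schedule$interval + 1e-9)
           schedule$interval * seq_len(n)
         },
         timepoints = schedule$timepoints,
         threshold = NULL)
}
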
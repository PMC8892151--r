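#' Simulate one fermenting bottle under a venting schedule
#'
#' Discrete-step simulation of head-space pressure in a sealed fermentation
#' bottle. Gas evolves according to the derivative of the
#' exponential-with-lag model scaled by the incubated DM mass. At every step
#' the free (un-vented, un-sequestered) gas partitions between head-space
#' over-pressure (ideal gas: `P = v_excess * p_atm / headspace_volume`) and a
#' dissolved phase at linear equilibrium
#' (`dissolved = solubility_coeff * P`). At a vent event the head space
#' returns to zero over-pressure, a fraction `sequestration_frac` of the
#' then-dissolved gas is moved to the sequestered ledger, and the remainder
#' re-equilibrates. Recorded readings pass through the linear sensor model
#' with additive Gaussian noise.
#'
#' The step size is `min(reading interval, 0.05 h)` so the fast early phase
#' of fermentation is resolved; reading times are inserted into the step
#' grid exactly.
#'
#' @param params A [fermentation_params()].
#' @param apparatus An [apparatus_config()].
#' @param schedule A [venting_schedule()].
#' @param seed Optional integer; when given, `set.seed(seed)` is called so
#'   the log is bit-reproducible. When `NULL` the current RNG stream is used
#'   (as [generate_experiment()] does).
#' @param keep_steps If `TRUE`, attach the per-step conservation ledger
#'   (`$steps`) for diagnostic checks.
#' @return An object of class `bottle_log`: a list with `readings` (a
#'   data.frame `time_h`, `pressure_kPa`, `pressure_true_kPa`, `vented`),
#'   `truth` (ledger of produced / vented / dissolved / sequestered /
#'   residual_headspace volumes in mL at ambient pressure, plus the true
#'   parameters), and optionally `steps`.
#' @examples
#' log <- simulate_bottle(
#'   fermentation_params(200, 0.08, 2, 0.2),
#'   apparatus_config(noise_sd = 0),
#'   venting_schedule("interval", interval = 0.25, horizon = 48),
#'   seed = 1)
#' nrow(log$readings)  # 192
#' @export
simulate_bottle <- function(params, apparatus, schedule, seed = NULL,
                            keep_steps = FALSE) {
  stopifnot(inherits(params, "fermentation_params"),
            inherits(apparatus, "apparatus_config"),
            inherits(schedule, "venting_schedule"))
  if (!is.null(seed)) set.seed(seed)

  horizon <- schedule$horizon
  rt <- reading_times(schedule)
  if (!is.null(rt) && length(rt) && max(rt) > horizon + 1e-9)
    stop("schedule timepoints extend beyond the horizon")

  dt <- if (schedule$mode == "interval") min(schedule$interval, 0.05) else 0.05
  grid <- seq(dt, horizon, by = dt)
  if (abs(grid[length(grid)] - horizon) > 1e-9) grid <- c(grid, horizon)
  if (!is.null(rt)) grid <- sort(unique(c(grid, rt)))
  read_at <- if (is.null(rt)) rep(FALSE, length(grid)) else
    grid %in% rt

  Vh <- apparatus$headspace_volume
  patm <- apparatus$p_atm
  s <- apparatus$solubility_coeff
  f <- apparatus$sequestration_frac
  kappa <- Vh / patm + s  # free gas (mL) per kPa over-pressure

  gas_at <- function(t) params$dm_mass * predict_gp(
    kinetic_params(params$B_true, params$c_true, params$L_true), t)

  X <- 0          # free gas: head-space excess + dissolved (mL ambient)
  vented <- 0
  sequestered <- 0
  produced_prev <- 0

  n <- length(grid)
  r_time <- numeric(0); r_true <- numeric(0); r_vent <- integer(0)
  if (keep_steps)
    steps <- data.frame(time_h = grid, produced = NA_real_, vented = NA_real_,
                        dissolved = NA_real_, sequestered = NA_real_,
                        residual_headspace = NA_real_)

  for (k in seq_len(n)) {
    produced_k <- gas_at(grid[k])
    dv <- produced_k - produced_prev
    if (dv < -1e-12) stop("negative gas evolution: model misconfiguration")
    produced_prev <- produced_k
    X <- X + dv
    P <- X / kappa
    if (X < -1e-12) stop("negative free-gas volume: model misconfiguration")

    vent_now <- FALSE
    record_now <- FALSE
    if (schedule$mode == "threshold") {
      if (P >= schedule$threshold) { vent_now <- TRUE; record_now <- TRUE }
      if (k == n) record_now <- TRUE          # final reading, not vented
    } else if (read_at[k]) {
      record_now <- TRUE
      vent_now <- TRUE                        # vent follows every reading
    }

    if (record_now) {
      r_time <- c(r_time, grid[k])
      r_true <- c(r_true, P)
      r_vent <- c(r_vent, as.integer(vent_now))
    }
    if (vent_now) {
      vented <- vented + P * Vh / patm
      d <- s * P
      sequestered <- sequestered + f * d
      X <- (1 - f) * d
      P <- X / kappa
    }
    if (keep_steps) {
      steps$produced[k] <- produced_k
      steps$vented[k] <- vented
      steps$dissolved[k] <- s * P
      steps$sequestered[k] <- sequestered
      steps$residual_headspace[k] <- P * Vh / patm
    }
  }

  # relative sensor accuracy: noise SD scales with the reading,
  # noise_sd kPa at a 10-kPa reading (zero pressure reads exactly zero)
  noise <- if (apparatus$noise_sd > 0)
    stats::rnorm(length(r_true), 0, apparatus$noise_sd * pmax(r_true, 0) / 10)
  else rep(0, length(r_true))
  # gauge sensors cannot read meaningfully below ambient: clamp recorded
  # values at the -0.5 kPa noise floor
  recorded <- pmax(-0.5, apparatus$sensor_gain * r_true +
                     apparatus$sensor_offset + noise)
  readings <- data.frame(
    time_h = r_time,
    pressure_kPa = recorded,
    pressure_true_kPa = r_true,
    vented = r_vent)

  P_final <- X / kappa
  truth <- list(
    params = params,
    produced = produced_prev,
    vented = vented,
    dissolved = s * P_final,
    residual_headspace = P_final * Vh / patm,
    sequestered = sequestered)
  out <- list(readings = readings, truth = truth, schedule_mode = schedule$mode)
  if (keep_steps) out$steps <- steps
  class(out) <- "bottle_log"
  out
}

#' @export
print.bottle_log <- function(x, ...) {
  cat("<bottle_log>", nrow(x$readings), "readings;",
      sprintf("produced %.2f mL, vented %.2f mL, sequestered %.2f mL\n",
              x$truth$produced, x$truth$vented, x$truth$sequestered))
  invisible(x)
}

#' Experiment design table for one measurement technique
#'
#' One row per bottle: `n_runs` incubation runs crossed with the feed list
#' and `n_reps` replicates, plus `n_blanks` blank bottles (buffered rumen
#' fluid only) split evenly across runs.
#'
#' @param n_runs Number of incubation runs (>= 1).
#' @param feeds Character vector of feed identifiers.
#' @param n_reps Replicates per run per feed (>= 1).
#' @param n_blanks Total blank bottles for this technique (>= 0).
#' @param technique Label, e.g. `"automated"` or `"manual"`.
#' @param dm_mass Incubated DM mass (g) for feed bottles; blanks get `NA`.
#' @return A data.frame with columns `bottle_id`, `run`, `technique`,
#'   `feed_id` (`"blank"` for blanks), `replicate`, `dm_mass`.
#' @examples
#' d <- generate_design(2, paste0("feed", 1:6), 4, 12, "automated")
#' nrow(d)  # 60
#' @export
generate_design <- function(n_runs, feeds, n_reps, n_blanks = 0,
                            technique = "automated", dm_mass = 0.2) {
  stopifnot(n_runs >= 1, n_reps >= 1, n_blanks >= 0)
  feeds <- as.character(feeds)
  if (length(feeds) == 0 && n_blanks == 0)
    stop("design is empty: no feeds and no blanks")
  rows <- list()
  if (length(feeds)) {
    rows[[1]] <- expand.grid(run = seq_len(n_runs), feed_id = feeds,
                             replicate = seq_len(n_reps),
                             KEEP.OUT.ATTRS = FALSE,
                             stringsAsFactors = FALSE)
    rows[[1]]$dm_mass <- dm_mass
  }
  if (n_blanks > 0) {
    blanks <- data.frame(
      run = sort(rep_len(seq_len(n_runs), n_blanks)),
      feed_id = "blank",
      replicate = stats::ave(seq_len(n_blanks),
                             sort(rep_len(seq_len(n_runs), n_blanks)),
                             FUN = seq_along),
      dm_mass = NA_real_)
    rows[[length(rows) + 1L]] <- blanks
  }
  design <- do.call(rbind, rows)
  design <- design[order(design$run, design$feed_id, design$replicate), ]
  design$technique <- technique
  design$bottle_id <- sprintf("%s_r%d_%s_%02d", technique, design$run,
                              design$feed_id, design$replicate)
  rownames(design) <- NULL
  design[, c("bottle_id", "run", "technique", "feed_id", "replicate",
             "dm_mass")]
}

#' Default true kinetic parameters for the six experimental feeds
#'
#' Asymptotic GP, rate and lag chosen to span the range typical of ruminant
#' feeds, from slowly fermenting wheat straw to rapidly fermenting cereal
#' grains; they echo the observed ranking grain > TMR > silage > hay >
#' straw.
#'
#' @param dm_mass Incubated DM mass (g) applied to every feed.
#' @return Named list of [fermentation_params()], one per feed.
#' @export
default_feed_params <- function(dm_mass = 0.2) {
  spec <- list(
    alfalfa_hay  = c(230, 0.090, 1.5),
    wheat_straw  = c(250, 0.035, 4.0),
    corn_silage  = c(245, 0.080, 2.0),
    barley_grain = c(310, 0.100, 1.5),
    corn_grain   = c(315, 0.105, 2.0),
    tmr          = c(270, 0.095, 1.5))
  lapply(spec, function(v)
    fermentation_params(v[1], v[2], v[3], dm_mass = dm_mass))
}

#' Simulate a full designed experiment
#'
#' Composes [simulate_bottle()] over a design table, adding multiplicative
#' random effects on the asymptotic GP: a run effect, a run-by-feed effect
#' and a replicate (bottle) effect, each lognormal-free Gaussian
#' multipliers centred at 1. Blanks ferment a small absolute gas volume
#' (residual substrate in the rumen fluid), share the run effect, and have
#' their own bottle-to-bottle variation.
#'
#' @param design Output of [generate_design()] (possibly several rbind-ed
#'   techniques — every row is simulated with the schedule of its
#'   technique).
#' @param feed_params Named list of [fermentation_params()] covering every
#'   feed in the design.
#' @param apparatus An [apparatus_config()] shared by all bottles, or a
#'   named list of configs keyed by technique.
#' @param schedules Named list of [venting_schedule()] keyed by technique.
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @param cv_run,cv_run_feed,cv_rep Coefficients of variation of the run,
#'   run-by-feed and replicate multipliers on `B_true`.
#' @param blank_params [fermentation_params()] for blank bottles, in
#'   absolute mL (`dm_mass = 1`).
#' @param cv_blank CV of the blank bottle multiplier.
#' @return A list with `logs` (named list of `bottle_log`) and `truth`
#'   (data.frame of per-bottle ground-truth parameters and final ledgers).
#' @export
generate_experiment <- function(design, feed_params = default_feed_params(),
                                apparatus = apparatus_config(),
                                schedules, seed = 1,
                                cv_run = 0.02, cv_run_feed = 0.02,
                                cv_rep = 0.09,
                                blank_params = fermentation_params(
                                  10, 0.05, 0, dm_mass = 1),
                                cv_blank = 0.05) {
  stopifnot(is.data.frame(design))
  feeds <- setdiff(unique(design$feed_id), "blank")
  missing <- setdiff(feeds, names(feed_params))
  if (length(missing))
    stop("no fermentation parameters for feed(s): ",
         paste(missing, collapse = ", "))
  techniques <- unique(design$technique)
  if (!all(techniques %in% names(schedules)))
    stop("missing schedule for technique(s): ",
         paste(setdiff(techniques, names(schedules)), collapse = ", "))
  app_for <- function(tech) {
    if (inherits(apparatus, "apparatus_config")) apparatus
    else apparatus[[tech]]
  }

  set.seed(seed)
  runs <- sort(unique(design$run))
  run_mult <- stats::setNames(stats::rnorm(length(runs), 1, cv_run),
                              as.character(runs))
  rf <- expand.grid(run = runs, feed_id = feeds, stringsAsFactors = FALSE)
  rf$mult <- stats::rnorm(nrow(rf), 1, cv_run_feed)

  logs <- vector("list", nrow(design))
  truth <- design
  truth$B_true <- NA_real_; truth$c_true <- NA_real_; truth$L_true <- NA_real_
  truth$produced <- NA_real_; truth$vented <- NA_real_
  truth$dissolved <- NA_real_; truth$sequestered <- NA_real_
  truth$residual_headspace <- NA_real_

  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    app <- app_for(row$technique)
    if (row$feed_id == "blank") {
      mult <- run_mult[[as.character(row$run)]] *
        stats::rnorm(1, 1, cv_blank)
      p <- fermentation_params(max(0, blank_params$B_true * mult),
                               blank_params$c_true, blank_params$L_true,
                               dm_mass = blank_params$dm_mass)
    } else {
      base <- feed_params[[row$feed_id]]
      mult <- run_mult[[as.character(row$run)]] *
        rf$mult[rf$run == row$run & rf$feed_id == row$feed_id] *
        stats::rnorm(1, 1, cv_rep)
      p <- fermentation_params(max(0, base$B_true * mult), base$c_true,
                               base$L_true, dm_mass = row$dm_mass)
    }
    log <- simulate_bottle(p, app, schedules[[row$technique]], seed = NULL)
    log$bottle_id <- row$bottle_id
    logs[[i]] <- log
    truth$B_true[i] <- p$B_true; truth$c_true[i] <- p$c_true
    truth$L_true[i] <- p$L_true
    truth$produced[i] <- log$truth$produced
    truth$vented[i] <- log$truth$vented
    truth$dissolved[i] <- log$truth$dissolved
    truth$sequestered[i] <- log$truth$sequestered
    truth$residual_headspace[i] <- log$truth$residual_headspace
  }
  names(logs) <- design$bottle_id
  list(logs = logs, truth = truth)
}

#' Generate a sensor calibration dataset
#'
#' Reproduces the bench calibration protocol: each sensor is driven through
#' applied pressures of 0, 5, 10, 15, 20 kPa ascending and 20, 15, 10, 5, 0
#' kPa descending, the whole cycle repeated twice — 20 records per sensor.
#' Raw digital readings follow the sensor's linear response plus Gaussian
#' noise.
#'
#' @param n_sensors Number of sensors (>= 1).
#' @param true_gains,true_offsets Per-sensor linear response; recycled to
#'   `n_sensors`. A zero gain is rejected (non-invertible sensor).
#' @param noise_sd Reading noise SD in raw units.
#' @param seed Optional seed.
#' @return data.frame `sensor_id`, `repetition`, `direction`, `applied_kPa`,
#'   `raw_reading`.
#' @examples
#' cal <- generate_calibration_dataset(36, seed = 1)
#' nrow(cal)  # 720
#' @export
generate_calibration_dataset <- function(n_sensors, true_gains = 1,
                                         true_offsets = 0, noise_sd = 0,
                                         seed = NULL) {
  stopifnot(n_sensors >= 1)
  gains <- rep_len(true_gains, n_sensors)
  offsets <- rep_len(true_offsets, n_sensors)
  if (any(gains == 0)) stop("sensor gain of 0 is not invertible")
  if (!is.null(seed)) set.seed(seed)
  applied <- c(0, 5, 10, 15, 20, 20, 15, 10, 5, 0)
  direction <- rep(c("ascending", "descending"), each = 5)
  one_rep <- data.frame(direction = direction, applied_kPa = applied)
  out <- do.call(rbind, lapply(seq_len(n_sensors), function(s) {
    do.call(rbind, lapply(1:2, function(r) {
      d <- one_rep
      d$sensor_id <- s
      d$repetition <- r
      d$raw_reading <- gains[s] * d$applied_kPa + offsets[s] +
        (if (noise_sd > 0) stats::rnorm(nrow(d), 0, noise_sd) else 0)
      d
    }))
  }))
  rownames(out) <- NULL
  out[, c("sensor_id", "repetition", "direction", "applied_kPa",
          "raw_reading")]
}

#' Flatten simulated logs to the long pressure-log table
#'
#' @param experiment Output of [generate_experiment()].
#' @return data.frame `run_id`, `technique`, `bottle_id`, `feed_id`,
#'   `replicate`, `time_h`, `pressure_kPa`, `vented`.
#' @export
pressure_log_table <- function(experiment) {
  truth <- experiment$truth
  do.call(rbind, lapply(seq_along(experiment$logs), function(i) {
    r <- experiment$logs[[i]]$readings
    data.frame(run_id = truth$run[i], technique = truth$technique[i],
               bottle_id = truth$bottle_id[i], feed_id = truth$feed_id[i],
               replicate = truth$replicate[i],
               time_h = r$time_h, pressure_kPa = r$pressure_kPa,
               vented = r$vented)
  }))
}
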
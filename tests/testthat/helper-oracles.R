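# Independent oracles and shared fixtures for the test suite.

# closed-form two-point calibration line through (raw1, p1), (raw2, p2)
two_point_calibration <- function(raw, applied) {
  i <- which(!duplicated(raw))[1:2]
  slope <- (applied[i[2]] - applied[i[1]]) / (raw[i[2]] - raw[i[1]])
  list(slope = slope, intercept = applied[i[1]] - slope * raw[i[1]])
}

# brute-force least squares over a parameter grid (oracle for fit_kinetics)
grid_search_kinetics <- function(times, gp, B_grid, c_grid, L_grid) {
  best <- NULL
  for (B in B_grid) for (cc in c_grid) for (L in L_grid) {
    pred <- ifelse(times <= L, 0, B * (1 - exp(-cc * (times - L))))
    rss <- sum((gp - pred)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(B = B, c = cc, L = L, rss = rss)
  }
  best
}

# the constructed 2 runs x 2 feeds x 2 reps dataset whose every cell
# contains {10, 12}: all cell means equal, within-cell variance 2
cells_10_12 <- function() {
  d <- expand.grid(run = 1:2, feed = c("a", "b"), rep = 1:2,
                   KEEP.OUT.ATTRS = FALSE)
  d$value <- ifelse(d$rep == 1, 10, 12)
  d
}

# simulate one dataset from the two-way random model
simulate_vc_dataset <- function(s2_run = 4, s2_feed = 100, s2_rf = 2,
                                s2_e = 9, r = 2, f = 6, n = 4) {
  run_eff <- rnorm(r, 0, sqrt(s2_run))
  feed_eff <- rnorm(f, 0, sqrt(s2_feed))
  rf_eff <- matrix(rnorm(r * f, 0, sqrt(s2_rf)), r, f)
  d <- expand.grid(run = seq_len(r), feed = seq_len(f), rep = seq_len(n),
                   KEEP.OUT.ATTRS = FALSE)
  d$value <- 100 + run_eff[d$run] + feed_eff[d$feed] +
    rf_eff[cbind(d$run, d$feed)] + rnorm(nrow(d), 0, sqrt(s2_e))
  d
}

# default schedules of the two techniques
auto_schedule <- function(horizon = 48)
  venting_schedule("interval", interval = 0.25, horizon = horizon)
manual_schedule <- function()
  venting_schedule("timepoints", timepoints = c(2, 4, 6, 8, 12, 16, 24, 36,
                                                48), horizon = 48)

quiet_apparatus <- function(...) apparatus_config(noise_sd = 0, ...)

# measured net cumulative GP (mL) at the last reading of a bottle log
measured_net_gp <- function(log, apparatus) {
  cum <- cumulate_pressure(log$readings$pressure_kPa, log$readings$time_h)
  utils::tail(pressure_to_volume(cum, apparatus$headspace_volume,
                                 apparatus$p_atm), 1)
}
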
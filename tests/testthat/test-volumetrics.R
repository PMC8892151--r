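test_that("cumulation runs the sum with the noise-floor clamp", {
  expect_equal(cumulate_pressure(c(2, 3, 1.5)), c(2, 5, 6.5))
  expect_equal(cumulate_pressure(c(0, 0, 0)), c(0, 0, 0))
  expect_equal(cumulate_pressure(c(2, -0.3, 1)), c(2, 2, 3))
  expect_error(cumulate_pressure(c(2, -0.7)), "sensor fault")
  expect_error(cumulate_pressure(c(1, 2), times = c(2, 2)), "increasing")
  # output is non-decreasing for any clamped input
  set.seed(1)
  x <- rnorm(100, 1, 1); x <- pmax(x, -0.49)
  expect_true(all(diff(cumulate_pressure(x)) >= 0))
})

test_that("pressure converts to volume under both conventions", {
  expect_equal(pressure_to_volume(0, 80, 101.325, "gross"), 80)
  expect_equal(pressure_to_volume(0, 80, 101.325, "net"), 0)
  expect_equal(pressure_to_volume(101.325, 80, 101.325, "gross"), 160)
  expect_equal(pressure_to_volume(101.325, 80, 101.325, "net"), 80)
  expect_equal(pressure_to_volume(50, 80, 100, "net"), 40)
  # gross - net = V0 identically, and net is linear in pressure
  p <- seq(0, 60, by = 7.3)
  expect_equal(pressure_to_volume(p, 80, 101.325, "gross") -
                 pressure_to_volume(p, 80, 101.325, "net"),
               rep(80, length(p)))
  expect_equal(pressure_to_volume(2 * p, 80, 101.325, "net"),
               2 * pressure_to_volume(p, 80, 101.325, "net"))
  expect_error(pressure_to_volume(10, 0, 101.325), "positive")
  expect_error(pressure_to_volume(10, 80, 0), "positive")
})

test_that("per-gram normalization divides by the incubated DM mass", {
  expect_equal(normalize_per_dm(40, 0.2), 200)
  expect_equal(normalize_per_dm(37, 0.185), 200)
  expect_equal(normalize_per_dm(0, 0.3), 0)
  expect_error(normalize_per_dm(10, 0), "positive")
})

test_that("blank correction subtracts the run's blank mean on a shared grid", {
  grid <- c(6, 12, 24)
  feed <- data.frame(time_h = grid, gp_mL = c(100, 100, 100))
  blanks <- lapply(c(6, 8, 10), function(v)
    data.frame(time_h = grid, gp_mL = rep(v, 3)))
  out <- blank_correct(feed, blanks)
  expect_equal(out$gp_mL, rep(92, 3))
  expect_true(all(out$blank_corrected))
  # a feed equal to the blank mean corrects to zero
  feed0 <- data.frame(time_h = grid, gp_mL = rep(8, 3))
  expect_equal(blank_correct(feed0, blanks)$gp_mL, rep(0, 3))
  expect_error(blank_correct(feed, list()), "no blank")
  shifted <- list(data.frame(time_h = grid + 1, gp_mL = rep(8, 3)))
  expect_error(blank_correct(feed, shifted), "grids")
})

test_that("corrected blanks of a simulated run average exactly zero", {
  design <- generate_design(2, c("hay", "grain"), 2, 4, "automated")
  fp <- list(hay = fermentation_params(200, 0.08, 2),
             grain = fermentation_params(300, 0.1, 1.5))
  sch <- list(automated = venting_schedule("interval", interval = 1,
                                           horizon = 24))
  exp <- generate_experiment(design, fp, apparatus_config(),
                             schedules = sch, seed = 5)
  gp <- build_gp_table(pressure_log_table(exp), design, 80)
  gp <- blank_correct_table(gp, design)
  bl <- gp[gp$feed_id == "blank", ]
  means <- tapply(bl$gp_mL, list(bl$run_id, bl$time_h), mean)
  expect_lt(max(abs(means)), 1e-9)
})

test_that("measured GP matches the produced-gas ledger when nothing is lost", {
  p <- fermentation_params(200, 0.08, 2, 0.2)
  app <- quiet_apparatus(sequestration_frac = 0)
  log <- simulate_bottle(p, app, auto_schedule())
  measured <- measured_net_gp(log, app)
  final_P <- utils::tail(log$readings$pressure_true_kPa, 1)
  tol <- app$solubility_coeff * final_P + 1e-9
  expect_lt(abs(measured - log$truth$produced), tol)
})

test_that("interpolation is exact on the grid and refuses extrapolation", {
  t <- c(24, 26); v <- c(100, 120)
  expect_equal(interpolate_gp(t, v, 24), 100)
  expect_equal(interpolate_gp(t, v, 25), 110)
  expect_error(interpolate_gp(t, v, 27), "extrapolation")
  # automated curve queried at the manual schedule: 9 non-decreasing values
  p <- fermentation_params(200, 0.08, 2, 0.2)
  app <- quiet_apparatus()
  log <- simulate_bottle(p, app, auto_schedule())
  cum <- cumulate_pressure(log$readings$pressure_kPa)
  gp <- pressure_to_volume(cum, app$headspace_volume, app$p_atm)
  q <- interpolate_gp(log$readings$time_h, gp,
                      c(2, 4, 6, 8, 12, 16, 24, 36, 48))
  expect_length(q, 9)
  expect_true(all(diff(q) >= 0))
})
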
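test_that("interval schedules follow the floor(horizon/interval) reading law", {
  cases <- list(c(0.25, 48, 192), c(1, 48, 48), c(3, 10, 3), c(0.5, 12, 24))
  p <- fermentation_params(200, 0.08, 2, 0.2)
  for (cs in cases) {
    sch <- venting_schedule("interval", interval = cs[1], horizon = cs[2])
    expect_length(reading_times(sch), cs[3])
    log <- simulate_bottle(p, quiet_apparatus(), sch, seed = 1)
    expect_equal(nrow(log$readings), cs[3])
  }
})

test_that("a zero-fermentation blank reads the sensor offset with empty ledgers", {
  app <- quiet_apparatus(sensor_offset = 1.5)
  log <- simulate_bottle(fermentation_params(0, 0.05, 0, 1), app,
                         auto_schedule(), seed = 3)
  expect_true(all(log$readings$pressure_kPa == 1.5))
  expect_equal(log$truth$produced, 0)
  expect_equal(log$truth$vented, 0)
  expect_equal(log$truth$sequestered, 0)
  expect_equal(log$truth$dissolved, 0)
})

test_that("design tables reproduce the replicated run-by-feed layout", {
  d <- generate_design(2, paste0("f", 1:6), 4, 12, "automated")
  expect_equal(nrow(d), 60)
  per_feed <- table(d$feed_id[d$feed_id != "blank"])
  expect_true(all(per_feed == 8))
  expect_equal(sum(d$feed_id == "blank"), 12)
  expect_equal(as.vector(table(d$run[d$feed_id == "blank"])), c(6L, 6L))
  expect_true(all(is.na(d$dm_mass[d$feed_id == "blank"])))
  expect_equal(nrow(generate_design(1, "hay", 1, 0)), 1)
  expect_error(generate_design(1, character(0), 1, 0), "empty")
})

test_that("the calibration generator follows the bench protocol counts", {
  expect_equal(nrow(generate_calibration_dataset(36, seed = 1)), 720)
  one <- generate_calibration_dataset(1)
  expect_equal(nrow(one), 20)
  expect_equal(sort(unique(one$applied_kPa)), c(0, 5, 10, 15, 20))
  expect_equal(as.vector(table(one$direction)), c(10L, 10L))
  # identity sensor without noise reads the applied pressure exactly
  expect_equal(one$raw_reading, one$applied_kPa)
  expect_error(generate_calibration_dataset(2, true_gains = c(1, 0)),
               "invertible")
})

test_that("gas is conserved at every simulation step across venting modes", {
  p <- fermentation_params(200, 0.08, 2, 0.2)
  app <- quiet_apparatus()
  schedules <- list(auto_schedule(), manual_schedule(),
                    venting_schedule("threshold", threshold = 4.5,
                                     horizon = 48))
  for (sch in schedules) {
    log <- simulate_bottle(p, app, sch, seed = 1, keep_steps = TRUE)
    err <- with(log$steps, abs(produced - (vented + residual_headspace +
                                             dissolved + sequestered)))
    expect_lt(max(err), 1e-9)
  }
})

test_that("without sequestration the schedule changes recovery only by the final dissolved gas", {
  p <- fermentation_params(200, 0.08, 2, 0.2)
  app <- quiet_apparatus(sequestration_frac = 0)
  recovered <- vapply(list(auto_schedule(), manual_schedule()), function(sch) {
    tr <- simulate_bottle(p, app, sch)$truth
    tr$vented + tr$residual_headspace
  }, numeric(1))
  final_P <- vapply(list(auto_schedule(), manual_schedule()), function(sch) {
    r <- simulate_bottle(p, app, sch)$readings
    utils::tail(r$pressure_true_kPa, 1)
  }, numeric(1))
  tol <- app$solubility_coeff * max(final_P)
  expect_lt(abs(recovered[1] - recovered[2]), tol + 1e-9)
})

test_that("recovered gas is monotone non-increasing in the venting interval", {
  p <- fermentation_params(200, 0.08, 2, 0.2)
  app <- quiet_apparatus()          # sequestration_frac 0.3
  rec <- vapply(c(0.25, 1, 4, 8), function(iv) {
    tr <- simulate_bottle(p, app, venting_schedule("interval", interval = iv,
                                                   horizon = 48))$truth
    tr$vented + tr$residual_headspace
  }, numeric(1))
  expect_true(all(diff(rec) <= 1e-12))
})

test_that("frequent automated venting recovers more gas than the manual timepoints", {
  p <- fermentation_params(200, 0.08, 2, 0.2)
  app <- quiet_apparatus(solubility_coeff = 0.5, sequestration_frac = 0.3)
  a <- simulate_bottle(p, app, auto_schedule(), seed = 0)$truth
  m <- simulate_bottle(p, app, manual_schedule(), seed = 0)$truth
  expect_gt(a$vented + a$residual_headspace,
            m$vented + m$residual_headspace)
})

test_that("experiments are bit-reproducible under a fixed seed", {
  design <- generate_design(1, c("hay", "straw"), 2, 2, "automated")
  fp <- list(hay = fermentation_params(200, 0.08, 2),
             straw = fermentation_params(150, 0.03, 4))
  sch <- list(automated = venting_schedule("interval", interval = 2,
                                           horizon = 24))
  e1 <- generate_experiment(design, fp, apparatus_config(),
                            schedules = sch, seed = 11)
  e2 <- generate_experiment(design, fp, apparatus_config(),
                            schedules = sch, seed = 11)
  expect_identical(e1, e2)
  # conservation holds for every bottle of the experiment
  for (tr in list(e1$truth)) {
    err <- abs(tr$produced - (tr$vented + tr$residual_headspace +
                                tr$dissolved + tr$sequestered))
    expect_lt(max(err), 1e-9)
  }
})

test_that("experiment generation names missing feed parameters and schedules", {
  design <- generate_design(1, "hay", 1, 0, "automated")
  sch <- list(automated = auto_schedule())
  expect_error(generate_experiment(design, list(), schedules = sch),
               "hay")
  expect_error(generate_experiment(
    design, list(hay = fermentation_params(200, 0.08, 2)),
    schedules = list()), "automated")
})

test_that("schedule validation rejects inconsistent inputs", {
  expect_error(venting_schedule("timepoints", timepoints = c(2, 50),
                                horizon = 48), "beyond")
  expect_error(venting_schedule("timepoints", timepoints = c(4, 2)),
               "increasing")
  expect_error(venting_schedule("interval", interval = 0), "positive")
  expect_error(venting_schedule("interval", horizon = -1), "positive")
})
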
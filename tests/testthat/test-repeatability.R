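test_that("the constructed {10,12}-cell design has pure residual variance", {
  d <- cells_10_12()
  # the raw run:feed moment estimate is -1 here; truncation warns by design
  expect_warning(vc <- estimate_variance_components(d, method = "anova_ems"),
                 "truncated")
  expect_equal(vc$sigma2_error, 2)
  expect_equal(vc$sigma2_run, 0)
  expect_equal(vc$sigma2_feed, 0)
  expect_equal(vc$sigma2_run_feed, 0)
  expect_equal(repeatability_rt(vc), 4)
  expect_equal(repeatability_pct(vc), 0)
})

test_that("identical observations give all-zero components and undefined RT%", {
  d <- cells_10_12()
  d$value <- 7
  vc <- estimate_variance_components(d, method = "anova_ems")
  expect_equal(vc$sigma2_error, 0)
  expect_equal(vc$sigma2_run + vc$sigma2_feed + vc$sigma2_run_feed, 0)
  expect_error(repeatability_pct(vc), "undefined")
})

test_that("REML coincides with the EMS solution on balanced interior data", {
  set.seed(10)
  d <- simulate_vc_dataset(s2_run = 200, s2_feed = 400, s2_rf = 50,
                           s2_e = 4, r = 4, f = 5, n = 3)
  ems <- estimate_variance_components(d, method = "anova_ems")
  reml <- estimate_variance_components(d, method = "reml")
  expect_false(any(ems$truncated))
  for (f in c("sigma2_run", "sigma2_feed", "sigma2_run_feed",
              "sigma2_error"))
    expect_equal(reml[[f]], ems[[f]], tolerance = 1e-6)
})

test_that("balanced REML agrees with the lme4 mixed-model fit", {
  set.seed(10)
  d <- simulate_vc_dataset(s2_run = 200, s2_feed = 400, s2_rf = 50,
                           s2_e = 4, r = 4, f = 5, n = 3)
  mine <- estimate_variance_components(d, method = "reml")
  fit <- suppressWarnings(lme4::lmer(
    value ~ 1 + (1 | run) + (1 | feed) + (1 | run:feed), data = d,
    REML = TRUE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  get <- function(g) vc$vcov[vc$grp == g]
  expect_equal(mine$sigma2_run, get("run"), tolerance = 1e-3)
  expect_equal(mine$sigma2_feed, get("feed"), tolerance = 1e-3)
  expect_equal(mine$sigma2_run_feed, get("run:feed"), tolerance = 1e-3)
  expect_equal(mine$sigma2_error, get("Residual"), tolerance = 1e-3)
})

test_that("unbalanced data are routed to REML and still estimable", {
  set.seed(11)
  d <- simulate_vc_dataset(r = 2, f = 3, n = 3)
  d <- d[-1, ]                      # break the balance
  expect_error(estimate_variance_components(d, method = "anova_ems"),
               "reml")
  vc <- estimate_variance_components(d, method = "reml")
  expect_gte(vc$sigma2_error, 0)
})

test_that("degenerate designs are rejected", {
  d <- cells_10_12()
  expect_error(estimate_variance_components(d[d$run == 1, ]), "2 runs")
  single <- d[d$rep == 1, ]
  expect_error(estimate_variance_components(single), "single replicate")
})

test_that("negative method-of-moments components are truncated with a warning", {
  # cell means far apart between feeds but runs identical: run component
  # estimate goes negative
  d <- expand.grid(run = 1:2, feed = c("a", "b"), rep = 1:3,
                   KEEP.OUT.ATTRS = FALSE)
  set.seed(12)
  d$value <- ifelse(d$feed == "a", 10, 50) + rnorm(nrow(d), 0, 4)
  expect_warning(vc <- estimate_variance_components(d, "anova_ems"),
                 "truncated")
  expect_gte(vc$sigma2_run, 0)
  expect_gte(vc$sigma2_run_feed, 0)
})

test_that("repeatability statistics follow their closed forms", {
  expect_equal(repeatability_rt(list(sigma2_error = 2)), 4)
  expect_equal(repeatability_rt(list(sigma2_error = 0)), 0)
  expect_equal(repeatability_rt(list(sigma2_error = 0.5)), 2)
  vc <- list(sigma2_run = 1, sigma2_feed = 2, sigma2_run_feed = 1,
             sigma2_error = 1)
  expect_equal(repeatability_pct(vc), 80)
  vc$sigma2_error <- 0
  expect_equal(repeatability_pct(vc), 100)
  # RT% decreases as residual variance grows, and stays in [0, 100]
  pcts <- vapply(c(0.1, 1, 10, 100), function(e)
    repeatability_pct(list(sigma2_run = 1, sigma2_feed = 2,
                           sigma2_run_feed = 1, sigma2_error = e)),
    numeric(1))
  expect_true(all(diff(pcts) < 0))
  expect_true(all(pcts >= 0 & pcts <= 100))
})

test_that("technique percent difference matches the published benchmark", {
  ref <- reference_technique_means()
  a <- ref$gp_mL_per_g[ref$technique == "automated" & ref$endpoint_h == 24]
  m <- ref$gp_mL_per_g[ref$technique == "manual" & ref$endpoint_h == 24]
  expect_equal(round(technique_pct_diff(a, m), 1), 11.5)
  expect_equal(technique_pct_diff(100, 100), 0)
})

test_that("identical techniques summarize to zero percent difference", {
  design <- generate_design(2, c("hay", "grain"), 2, 4, "automated")
  fp <- list(hay = fermentation_params(200, 0.08, 2),
             grain = fermentation_params(300, 0.1, 1.5))
  sch <- list(automated = venting_schedule("interval", interval = 1,
                                           horizon = 24))
  exp <- generate_experiment(design, fp, apparatus_config(),
                             schedules = sch, seed = 6)
  gp <- blank_correct_table(build_gp_table(pressure_log_table(exp),
                                           design, 80), design)
  twin <- gp
  twin$technique <- "manual"
  twin$bottle_id <- paste0("m_", twin$bottle_id)
  both <- rbind(gp, twin)
  s <- technique_feed_means(both, endpoints = c(6, 12, 24))
  expect_equal(unname(s$pct_diff), rep(0, 3))
  expect_error(technique_feed_means(gp, endpoints = c(6, 12, 24)),
               "technique level")
})

test_that("higher sensor noise inflates residual variance and RT, deflates RT%", {
  design <- rbind(generate_design(2, c("hay", "grain", "tmr"), 2, 4,
                                  "automated"),
                  generate_design(2, c("hay", "grain", "tmr"), 2, 4,
                                  "manual"))
  fp <- list(hay = fermentation_params(200, 0.08, 2),
             grain = fermentation_params(300, 0.1, 1.5),
             tmr = fermentation_params(250, 0.09, 1.5))
  sch <- list(automated = venting_schedule("interval", interval = 1,
                                           horizon = 24),
              manual = venting_schedule("timepoints",
                                        timepoints = c(2, 4, 8, 12, 24),
                                        horizon = 24))
  # biological variation switched off so the residual variance isolates the
  # sensor-noise contribution
  rep_at <- function(noise) {
    exp <- generate_experiment(design, fp,
                               apparatus = apparatus_config(noise_sd = noise),
                               schedules = sch, seed = 13,
                               cv_run = 0, cv_run_feed = 0, cv_rep = 0,
                               cv_blank = 0)
    gp <- blank_correct_table(build_gp_table(pressure_log_table(exp),
                                             design, 80), design)
    repeatability_report(gp, endpoints = 24, method = "anova_ems")
  }
  lo <- suppressWarnings(rep_at(0.05))
  hi <- suppressWarnings(rep_at(3))
  expect_true(all(hi$sigma2_error > lo$sigma2_error))
  expect_true(all(hi$RT > lo$RT))
  expect_true(all(hi$RT_pct < lo$RT_pct))
})
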
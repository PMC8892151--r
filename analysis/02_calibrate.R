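#!/usr/bin/env Rscript
# Stage 2 — per-sensor calibration lines and quality checks.
#
# Fits the raw->kPa conversion for each of the 36 sensors from the bench
# protocol (0..20 kPa ascending/descending, twice), reports fit quality and
# hysteresis, and demonstrates the leak and ideal-gas response checks.

library(gasferm)

cal_data <- read.csv("results/calibration.csv")
cals <- fit_all_calibrations(cal_data)
tab <- do.call(rbind, lapply(cals, function(c)
  data.frame(sensor_id = c$sensor_id, slope = c$slope,
             intercept = c$intercept, r_squared = c$r_squared,
             hysteresis = c$hysteresis)))
write.csv(tab, "results/sensor_calibrations.csv", row.names = FALSE)

cat(nrow(tab), "conversion equations fitted\n")
cat("slope range:", round(range(tab$slope), 4), "\n")
cat("min r-squared:", format(min(tab$r_squared), digits = 6), "\n")
cat("max hysteresis:", round(max(tab$hysteresis), 4), "kPa\n")

# leak test: a tight bottle pressurized to 90 kPa and watched overnight
t <- seq(0, 16, by = 0.25)
tight <- leak_test(t, rep(90, length(t)))
cat("leak test (tight bottle): pass =", tight$pass,
    ", max drop =", tight$max_drop, "kPa\n")

# response check: 8 mL air into an 80-mL head space should read ~10.13 kPa
res <- response_check(cals[[1]], known_headspace_mL = 80,
                      injected_air_mL = 8,
                      raw_reading = (10.1325 - cals[[1]]$intercept) /
                        cals[[1]]$slope)
cat("response check: expected", round(res$expected_kPa, 4), "kPa, drift =",
    res$drift, "\n")
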
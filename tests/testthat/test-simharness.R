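test_that("the deep-hypothermia run walks the full phase sequence", {
  res <- reference_run()
  # cooling engages on the first tick, so the recorded sequence starts
  # there; order must be a strict subsequence of the protocol order
  seq_phases <- rle(res$series$phase)$values
  expect_equal(seq_phases,
               c("COOLING", "MAINTENANCE", "REWARMING",
                 "FINAL_REWARMING", "WEANING"))
})

test_that("perfect sensing yields full compliance and no safety alarms", {
  res <- reference_run()
  expect_equal(res$metrics$gradient_compliance, 1.0)
  counts <- res$metrics$alarm_counts
  expect_equal(unname(counts["gradient_breach"] + counts["rate_breach"] +
                        counts["temp_bound"] + counts["rewarm_rate"]),
               0L)
  # commanded setpoints stay inside the absolute bounds
  expect_gte(min(res$series$hcu_setpoint), 18)
  expect_lte(max(res$series$hcu_setpoint), 37)
})

test_that("phase-appropriate policies are applied along the run", {
  s <- reference_run()$series
  deep <- s$phase == "MAINTENANCE"
  expect_true(all(s$ph_strategy[deep] == "pH-stat"))
  expect_true(all(s$ph_strategy[s$fused_core > 34] == "alpha-stat"))
  # flow follows the policy reduction at depth (20 C -> 37.5% of standard)
  expect_equal(stats::median(s$flow_fraction[deep]), 0.375, tolerance = 0.02)
  expect_true(all(s$do2_delivered >= s$do2_floor - 1e-9))
})

test_that("identical seeds reproduce the run bit for bit", {
  sc <- reference_scenario(seed = 21L)
  cfg <- sim_config()
  r1 <- run_scenario(sc, cfg)
  r2 <- run_scenario(sc, cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$config_hash, r2$config_hash)
})

test_that("a normothermic target from a normothermic start idles safely", {
  sc <- scenario(name = "normothermia", target_core_temp = 37,
                 rewarm_permitted_min = 0, duration_min = 20, seed = 3L,
                 deep_hypothermia = FALSE)
  res <- run_scenario(sc, perfect_config())
  expect_true(all(res$series$phase == "STANDBY"))
  expect_equal(res$metrics$gradient_compliance, 1.0)
})

test_that("rate-limited cooling cannot beat the analytic lower bound", {
  res <- cooling_run() # 37 -> 28 at 1 C per 4 min
  expect_gte(res$metrics$time_to_target_min, 9 * 4)
})

test_that("compliance counts breach ticks over constrained ticks", {
  # constructed fixture: 100 cooling ticks of which exactly 3 breach,
  # plus unconstrained maintenance ticks that must not dilute the metric
  n <- 120
  ser <- data.frame(
    time_s = seq_len(n) - 1,
    t_arterial = rep(30, n), t_venous = 30, t_core = 30,
    t_peripheral = 30,
    t_hcu_water = rep(25, n),
    fused_core = 30, hcu_setpoint = 25, flow_fraction = 1,
    do2_floor = 180,
    phase = c(rep("COOLING", 100), rep("MAINTENANCE", 20)),
    ph_strategy = "alpha-stat", stringsAsFactors = FALSE)
  ser$t_hcu_water[c(10, 50, 90)] <- 19.5 # gradient 10.5 C
  expect_equal(gradient_compliance(ser), 0.97)
  # maintenance-only series is vacuously compliant
  ser2 <- ser[101:120, ]
  expect_equal(gradient_compliance(ser2), 1.0)
  expect_error(gradient_compliance(ser[0, ]), "non-empty")
  # audit mode on the written fixture reproduces the metric exactly
  path <- tempfile(fileext = ".csv")
  write_timeseries(ser, path)
  expect_identical(audit_timeseries(path), 0.97)
})

test_that("every sustained true gradient breach produces an alarm", {
  # fault injection: an operator override pins the water 8 C above the
  # core during rewarming, so the true blood-core gradient genuinely
  # breaches; the alarm engine watches ground truth and must catch every
  # sustained breach, and the compliance metric must record it
  cfg <- controller_config(target_core_temp = 28)
  saf <- safety_config()
  pol <- default_policy_table()
  p <- patient_params()
  eng <- alarm_engine(saf)
  st <- thermal_state(28, 28, 28, 28, 28)
  forced <- apply_override(override_command(manual_hcu_setpoint = 36,
                                            issued_by = "test"),
                           controller_command(hcu_setpoint = 32,
                                              flow_fraction = 0.9,
                                              phase = "REWARMING"),
                           cfg)
  n <- 600
  ser <- data.frame(time_s = seq_len(n) - 1, t_arterial = NA_real_,
                    t_venous = NA_real_, t_core = NA_real_,
                    t_peripheral = NA_real_, t_hcu_water = NA_real_,
                    fused_core = NA_real_, hcu_setpoint = 36,
                    flow_fraction = 0.9, do2_floor = 180,
                    phase = "REWARMING", ph_strategy = "alpha-stat",
                    stringsAsFactors = FALSE)
  n_alarms <- 0L
  for (i in seq_len(n)) {
    fused <- list(core = st$t_core, blood = st$t_arterial,
                  degraded = FALSE, available = TRUE)
    out <- check_alarms(st, fused, forced, cfg, saf, eng)
    eng <- out$engine
    n_alarms <- n_alarms + sum(out$events$kind == "gradient_breach")
    ser$t_arterial[i] <- st$t_arterial
    ser$t_venous[i] <- st$t_venous
    ser$t_core[i] <- st$t_core
    ser$t_peripheral[i] <- st$t_peripheral
    ser$t_hcu_water[i] <- st$t_hcu_water
    ser$fused_core[i] <- st$t_core
    st <- step_thermal(st, forced, p)
  }
  breach <- ser$t_arterial - ser$t_core > 4
  runs <- rle(breach)
  expect_gte(max(runs$lengths[runs$values]), 3) # a sustained breach exists
  expect_gte(n_alarms, 1)
  expect_lt(gradient_compliance(ser), 1)
})

test_that("the time series round-trips and audits identically", {
  res <- cooling_run()
  path <- tempfile(fileext = ".csv")
  write_timeseries(res, path)
  back <- read_timeseries(path)
  expect_equal(back$t_arterial, res$series$t_arterial, tolerance = 1e-6)
  expect_equal(back$phase, res$series$phase)
  expect_identical(audit_timeseries(path),
                   res$metrics$gradient_compliance)

  # header and row validation
  lines <- readLines(path)
  bad <- tempfile(fileext = ".csv")
  writeLines(c(sub("time_s", "t", lines[1]), lines[-1]), bad)
  expect_error(read_timeseries(bad), "header")
  writeLines(c(lines[1:10], substr(lines[11], 1, 20)), bad)
  expect_error(read_timeseries(bad), "line 11")
})

test_that("a single-run study reproduces run_scenario", {
  sc <- scenario(target_core_temp = 28, rewarm_permitted_min = 1e6,
                 duration_min = 50, seed = 13L,
                 deep_hypothermia = FALSE)
  cfg <- sim_config()
  st <- dropout_study(1, sc, cfg, base_seed = 13)
  direct <- run_scenario(sc, cfg)
  expect_identical(st$runs$compliance,
                   direct$metrics$gradient_compliance)
  expect_identical(st$mean_compliance, st$min_compliance)
})

test_that("zero dropout keeps the study fully compliant", {
  sc <- scenario(target_core_temp = 28, rewarm_permitted_min = 45,
                 duration_min = 90, seed = 2L, deep_hypothermia = FALSE)
  cfg <- sim_config(sensors = sensor_model(dropout_rate_per_hour = 0,
                                           noise_sd = 0, lag_s = 0))
  st <- dropout_study(2, sc, cfg, base_seed = 100)
  expect_equal(st$mean_compliance, 1.0)
})

test_that("circulatory arrest forces zero flow over its interval", {
  sc <- scenario(target_core_temp = 20, rewarm_permitted_min = 1e6,
                 duration_min = 30, seed = 4L,
                 circulatory_arrest = c(10, 15))
  res <- run_scenario(sc, perfect_config())
  s <- res$series
  inside <- s$time_s >= 600 & s$time_s < 900
  expect_true(all(s$flow_fraction[inside] == 0))
  expect_true(all(s$flow_fraction[s$time_s < 600] > 0))
})

test_that("scenario and config validation reject bad inputs", {
  expect_error(scenario(target_core_temp = 10), "\\[18, 37\\]")
  expect_error(scenario(duration_min = 0))
  expect_error(scenario(circulatory_arrest = c(15, 10)))
  expect_error(sim_config(dt = 0))
})
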
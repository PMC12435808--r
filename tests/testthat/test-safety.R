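ok_fused <- list(core = 30, blood = 30, degraded = FALSE, available = TRUE)

mk_state <- function(ta = 30, tc = 30, tw = 28, time = 0) {
  list(t_arterial = ta, t_venous = ta, t_core = tc, t_peripheral = tc,
       t_hcu_water = tw, time = time)
}

mk_cmd <- function(phase = "COOLING", setpoint = 28) {
  controller_command(hcu_setpoint = setpoint, phase = phase,
                     do2_floor = 180)
}

test_that("gradient breaches fire only after the debounce persists", {
  cfg <- controller_config(target_core_temp = 28)
  saf <- safety_config(debounce_ticks = 3)
  eng <- alarm_engine(saf)
  st <- mk_state(ta = 37, tw = 26.5) # blood-water gradient 10.5 C
  cmd <- mk_cmd("COOLING")
  for (i in 1:2) {
    out <- check_alarms(st, ok_fused, cmd, cfg, saf, eng)
    eng <- out$engine
    expect_equal(nrow(out$events), 0)
  }
  out <- check_alarms(st, ok_fused, cmd, cfg, saf, eng)
  expect_equal(out$events$kind, "gradient_breach")
  expect_equal(out$events$severity, "critical")
  # already fired: stays silent while the condition persists
  out2 <- check_alarms(st, ok_fused, cmd, cfg, saf, out$engine)
  expect_equal(nrow(out2$events), 0)
})

test_that("a condition shorter than the debounce never fires", {
  cfg <- controller_config(target_core_temp = 28)
  saf <- safety_config(debounce_ticks = 3, hysteresis_ticks = 5)
  eng <- alarm_engine(saf)
  breach <- mk_state(ta = 37, tw = 26.5)
  calm <- mk_state(ta = 30, tw = 28)
  cmd <- mk_cmd("COOLING")
  seqs <- list(breach, calm, breach, calm, breach, calm)
  for (st in seqs) {
    out <- check_alarms(st, ok_fused, cmd, cfg, saf, eng)
    eng <- out$engine
    expect_equal(nrow(out$events), 0)
  }
})

test_that("hysteresis re-arms a kind only after a sustained clear", {
  cfg <- controller_config(target_core_temp = 28)
  saf <- safety_config(debounce_ticks = 1, hysteresis_ticks = 4)
  eng <- alarm_engine(saf)
  breach <- mk_state(ta = 37, tw = 26.5)
  calm <- mk_state(ta = 30, tw = 28)
  cmd <- mk_cmd("COOLING")
  out <- check_alarms(breach, ok_fused, cmd, cfg, saf, eng)
  expect_equal(out$events$kind, "gradient_breach")
  eng <- out$engine
  # clears for fewer ticks than the hysteresis: still disarmed
  for (i in 1:3) eng <- check_alarms(calm, ok_fused, cmd, cfg, saf,
                                     eng)$engine
  out <- check_alarms(breach, ok_fused, cmd, cfg, saf, eng)
  expect_equal(nrow(out$events), 0)
  eng <- out$engine
  # a full clear re-arms
  for (i in 1:4) eng <- check_alarms(calm, ok_fused, cmd, cfg, saf,
                                     eng)$engine
  out <- check_alarms(breach, ok_fused, cmd, cfg, saf, eng)
  expect_equal(out$events$kind, "gradient_breach")
})

test_that("rewarming gradient, DO2, rSO2 and sensor-loss conditions fire", {
  cfg <- controller_config(target_core_temp = 20)
  saf <- safety_config(debounce_ticks = 1)
  st <- mk_state(ta = 34.5, tc = 30, tw = 34)
  out <- check_alarms(st, ok_fused, mk_cmd("REWARMING"), cfg, saf)
  expect_true("gradient_breach" %in% out$events$kind)

  st_ok <- mk_state(ta = 31, tc = 30, tw = 33)
  out <- check_alarms(st_ok, ok_fused, mk_cmd("REWARMING"), cfg, saf,
                      context = list(do2_delivered = 150))
  expect_true("do2_deficit" %in% out$events$kind)
  out <- check_alarms(st_ok, ok_fused, mk_cmd("REWARMING"), cfg, saf,
                      context = list(rso2 = 40))
  expect_true("rso2_low" %in% out$events$kind)
  lost <- list(core = NA, blood = NA, degraded = TRUE, available = FALSE)
  out <- check_alarms(st_ok, lost, mk_cmd("REWARMING"), cfg, saf)
  expect_true("sensor_loss" %in% out$events$kind)
  # everything nominal: no events
  out <- check_alarms(st_ok, ok_fused, mk_cmd("REWARMING"), cfg, saf,
                      context = list(do2_delivered = 250, rso2 = 65,
                                     core_rise = 0.4, traj_change = 0.75))
  expect_equal(nrow(out$events), 0)
})

test_that("manual overrides are clamped to the absolute bounds and logged", {
  cfg <- controller_config(target_core_temp = 28)
  cmd <- mk_cmd("MAINTENANCE", setpoint = 28)
  ov <- override_command(manual_hcu_setpoint = 30, time = 100)
  out <- apply_override(ov, cmd, cfg)
  expect_equal(out$hcu_setpoint, 30)
  expect_equal(attr(out, "events")$severity, "advisory")
  # hyperthermic request is clamped to 37 and escalated
  ov <- override_command(manual_hcu_setpoint = 40, time = 101)
  out <- apply_override(ov, cmd, cfg)
  expect_equal(out$hcu_setpoint, 37)
  expect_equal(attr(out, "events")$severity, "warning")
  ov <- override_command(manual_hcu_setpoint = 5, time = 102)
  expect_equal(apply_override(ov, cmd, cfg)$hcu_setpoint, 18)
  # forced phase bypasses the legality table, logged critical
  ov <- override_command(force_phase = "STANDBY", time = 103)
  out <- apply_override(ov, cmd, cfg)
  expect_equal(out$phase, "STANDBY")
  expect_equal(attr(out, "events")$severity, "critical")
  expect_error(override_command(), "override")
})

test_that("the audit log round-trips events field for field", {
  set.seed(31)
  n <- 100
  ev <- data.frame(
    kind = sample(names(alarm_kinds), n, replace = TRUE),
    severity = sample(c("advisory", "warning", "critical"), n,
                      replace = TRUE),
    time = sort(round(stats::runif(n, 0, 7200), 3)),
    message = sprintf("event %d", seq_len(n)),
    acknowledged = sample(c(TRUE, FALSE), n, replace = TRUE),
    stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".jsonl")
  write_audit_log(ev, path)
  back <- read_audit_log(path)
  expect_equal(back, ev)
  # stable field order, one object per line
  first <- readLines(path, n = 1)
  expect_match(first,
               '^\\{"kind":.*"severity":.*"time":.*"message":.*"acknowledged":')
})

test_that("empty and out-of-order logs are handled per contract", {
  path <- tempfile(fileext = ".jsonl")
  write_audit_log(data.frame(kind = character(), severity = character(),
                             time = numeric(), message = character(),
                             acknowledged = logical()), path)
  expect_equal(nrow(read_audit_log(path)), 0)
  bad <- data.frame(kind = c("sensor_loss", "sensor_loss"),
                    severity = "warning", time = c(10, 5),
                    message = "x", acknowledged = FALSE,
                    stringsAsFactors = FALSE)
  expect_error(write_audit_log(bad, path), "time-ordered")
})
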
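#' Bypass scenario
#'
#' Describes one simulated bypass run. The default is the deep-hypothermia
#' reference scenario: cool from 37 C to a 20 C target (within the
#' customary 18-22 C deep-hypothermia band), maintain, rewarm to 32 C once
#' the surgical team permits (here, 90 min into bypass), final-rewarm to
#' 36-37 C, and wean.
#'
#' @param name scenario label.
#' @param initial_temp uniform initial temperature of all compartments, C.
#' @param target_core_temp target core temperature, C, within `[18, 37]`.
#' @param rewarm_permitted_min minutes after which rewarming is permitted.
#' @param duration_min simulated duration, minutes (> 0).
#' @param deep_hypothermia logical flag (metadata).
#' @param circulatory_arrest `NULL`, or a length-2 interval (minutes)
#'   during which pump flow is forced to zero.
#' @param seed RNG seed for the run.
#' @return An object of class `cpb_scenario`.
#' @export
scenario <- function(name = "deep_hypothermia",
                     initial_temp = 37,
                     target_core_temp = 20,
                     rewarm_permitted_min = 90,
                     duration_min = 260,
                     deep_hypothermia = TRUE,
                     circulatory_arrest = NULL,
                     seed = 1L) {
  stopifnot(is.finite(duration_min), duration_min > 0)
  if (target_core_temp < 18 || target_core_temp > 37)
    stop("target_core_temp must lie within [18, 37] C")
  if (!is.null(circulatory_arrest))
    stopifnot(length(circulatory_arrest) == 2,
              circulatory_arrest[1] < circulatory_arrest[2])
  structure(list(name = name, initial_temp = initial_temp,
                 target_core_temp = target_core_temp,
                 rewarm_permitted_min = rewarm_permitted_min,
                 duration_min = duration_min,
                 deep_hypothermia = isTRUE(deep_hypothermia),
                 circulatory_arrest = circulatory_arrest,
                 seed = as.integer(seed)),
            class = "cpb_scenario")
}

#' Bundle of all simulation configuration blocks
#'
#' @param patient a [patient_params()].
#' @param controller a [controller_config()].
#' @param sensors a [sensor_model()].
#' @param safety a [safety_config()].
#' @param policy a [policy_table()].
#' @param blood_gas a [blood_gas_params()].
#' @param dt simulation tick, s.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(patient = patient_params(),
                       controller = controller_config(),
                       sensors = sensor_model(),
                       safety = safety_config(),
                       policy = default_policy_table(),
                       blood_gas = blood_gas_params(),
                       dt = 1) {
  stopifnot(is.finite(dt), dt > 0)
  structure(list(patient = patient, controller = controller,
                 sensors = sensors, safety = safety, policy = policy,
                 blood_gas = blood_gas, dt = dt),
            class = "sim_config")
}

# md5 of the serialized configuration, for result provenance
.config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeBin(serialize(config, NULL, version = 2), tf)
  unname(tools::md5sum(tf))
}

.timeseries_columns <- c("time_s", "t_arterial", "t_venous", "t_core",
                         "t_peripheral", "t_hcu_water", "fused_core",
                         "hcu_setpoint", "flow_fraction", "do2_floor",
                         "phase", "ph_strategy")

#' Run one closed-loop scenario
#'
#' Executes the closed loop observe -> fuse -> transition ->
#' compute_command -> check_alarms -> step_thermal at the configured tick,
#' deterministic under the scenario seed. Any invariant violation inside a
#' module aborts with the tick index and a state dump in the error
#' message.
#'
#' @param scen a [scenario()].
#' @param config a [sim_config()]; the controller's target is taken from
#'   the scenario.
#' @return An object of class `simulation_result`: list with `series`
#'   (tick-level data frame), `events` (alarm log), `metrics` (gradient
#'   compliance, time to target, overshoot, alarm counts), `scenario`,
#'   `seed`, `config_hash`.
#' @export
run_scenario <- function(scen, config = sim_config()) {
  stopifnot(inherits(scen, "cpb_scenario"), inherits(config, "sim_config"))
  ctrl <- config$controller
  ctrl$target_core_temp <- scen$target_core_temp
  p <- config$patient
  sens <- config$sensors
  saf <- config$safety
  pol <- config$policy
  dt <- config$dt
  set.seed(scen$seed)

  n <- ceiling(scen$duration_min * 60 / dt)
  horizon <- n * dt
  mask <- dropout_process(sens, horizon, dt)
  noise <- matrix(stats::rnorm(n * 5), nrow = n, ncol = 5)
  noise <- sweep(noise, 2, sens$noise_sd, `*`)

  cao2 <- arterial_o2_content(config$blood_gas)
  win_ticks <- as.integer(round(saf$rewarm_rate_window_s / dt))
  wean_ticks <- as.integer(ceiling(ctrl$stability_window_min * 60 / dt))

  # preallocated series
  S <- list(time_s = numeric(n), t_arterial = numeric(n),
            t_venous = numeric(n), t_core = numeric(n),
            t_peripheral = numeric(n), t_hcu_water = numeric(n),
            fused_core = numeric(n), hcu_setpoint = numeric(n),
            flow_fraction = numeric(n), do2_floor = numeric(n),
            phase = character(n), ph_strategy = character(n),
            co2_strategy = character(n), traj_target = numeric(n),
            fused_blood = numeric(n), do2_delivered = numeric(n),
            rso2 = numeric(n), degraded = logical(n), hold = logical(n),
            core_full = logical(n))

  ta <- scen$initial_temp; tv <- ta; tc <- ta; tp <- ta; tw <- ta
  lag <- .site_truth(ta, tv, tc, tp, sens$bladder_core_weight)
  alpha <- ifelse(sens$lag_s > 0, pmin(dt / sens$lag_s, 1), 1)
  phase <- "STANDBY"
  command <- controller_command(hcu_setpoint = ta, phase = "STANDBY",
                                traj_target = tc)
  engine <- alarm_engine(saf)
  events <- vector("list", 64L); n_ev <- 0L
  do2_met <- logical(n)
  mfrac_cache_t <- NA_real_; mfrac_cache <- 1

  arrest <- scen$circulatory_arrest
  for (i in seq_len(n)) {
    t_now <- (i - 1) * dt

    # --- observe ---------------------------------------------------------
    truth <- .site_truth(ta, tv, tc, tp, sens$bladder_core_weight)
    lag <- lag + alpha * (truth - lag)
    value <- lag + sens$bias + noise[i, ]
    valid <- mask[i, ]
    fused <- .fuse_scalars(value, valid, ctrl$minimum_valid_core_sensors)

    # --- phase transition ------------------------------------------------
    flags <- list(rewarm_permitted = t_now >= scen$rewarm_permitted_min * 60)
    if (phase == "FINAL_REWARMING" && i > wean_ticks) {
      idx <- (i - wean_ticks):(i - 1)
      flags$weaning_ready <- weaning_ready(S$fused_core[idx],
                                           do2_met[idx], ctrl, dt)
    }
    phase <- transition(phase, fused, ctrl, flags)

    # --- command ---------------------------------------------------------
    command <- compute_command(phase, fused, ctrl, command, pol, dt)
    in_arrest <- !is.null(arrest) &&
      t_now >= arrest[1] * 60 && t_now < arrest[2] * 60
    if (in_arrest) command$flow_fraction <- 0

    do2_delivered <- command$flow_fraction * ctrl$standard_cardiac_index *
      cao2 * 10
    do2_met[i] <- do2_delivered >= command$do2_floor - 1e-9
    rso2 <- saf$rso2_baseline *
      (1 - 0.5 * max(0, 1 - do2_delivered / command$do2_floor))

    # --- alarms ----------------------------------------------------------
    traj_change <- if (i > win_ticks)
      command$traj_target - S$traj_target[i - win_ticks] else NA_real_
    # measured-rate check only across two full-quality estimates (all
    # three core sites valid): losing a site switches the median to a
    # two-site mean that includes the slow bladder probe, which can move
    # the estimate most of a degree with no real temperature change
    core_full <- valid[3] && valid[4] && valid[5]
    S$core_full[i] <- core_full
    core_rise <- if (i > win_ticks && is.finite(S$fused_core[i - win_ticks]) &&
                     isTRUE(fused$available) && core_full &&
                     S$core_full[i - win_ticks])
      fused$core - S$fused_core[i - win_ticks] else NA_real_
    st_now <- list(t_arterial = ta, t_venous = tv, t_core = tc,
                   t_peripheral = tp, t_hcu_water = tw, time = t_now)
    conds <- .alarm_conditions(st_now, fused, command, ctrl, saf,
                               list(traj_change = traj_change,
                                    core_rise = core_rise,
                                    do2_delivered = do2_delivered,
                                    rso2 = rso2))
    stp <- .alarm_engine_step(engine, conds)
    engine <- stp$engine
    if (length(stp$fired)) {
      for (k in stp$fired) {
        n_ev <- n_ev + 1L
        if (n_ev > length(events)) events <- c(events, vector("list", 64L))
        events[[n_ev]] <- data.frame(
          kind = k, severity = unname(alarm_kinds[k]), time = t_now,
          message = sprintf("%s at t=%.0fs (phase %s)", k, t_now, phase),
          acknowledged = FALSE, stringsAsFactors = FALSE)
      }
    }

    # --- record ----------------------------------------------------------
    S$time_s[i] <- t_now
    S$t_arterial[i] <- ta; S$t_venous[i] <- tv; S$t_core[i] <- tc
    S$t_peripheral[i] <- tp; S$t_hcu_water[i] <- tw
    S$fused_core[i] <- if (is.na(fused$core)) NA_real_ else fused$core
    S$fused_blood[i] <- if (is.na(fused$blood)) NA_real_ else fused$blood
    S$hcu_setpoint[i] <- command$hcu_setpoint
    S$flow_fraction[i] <- command$flow_fraction
    S$do2_floor[i] <- command$do2_floor
    S$phase[i] <- phase
    S$ph_strategy[i] <- command$ph_strategy
    S$co2_strategy[i] <- command$co2_strategy
    S$traj_target[i] <- command$traj_target
    S$do2_delivered[i] <- do2_delivered
    S$rso2[i] <- rso2
    S$degraded[i] <- isTRUE(fused$degraded)
    S$hold[i] <- isTRUE(command$hold)

    # --- step the patient ------------------------------------------------
    if (p$baseline_metabolic_rate > 0) {
      tcl <- min(max(tc, 10), 40)
      if (is.na(mfrac_cache_t) || abs(tcl - mfrac_cache_t) > 0.01) {
        mfrac_cache <- metabolic_fraction(tcl, pol)
        mfrac_cache_t <- tcl
      }
      mf <- mfrac_cache
    } else mf <- 0
    y <- .step_thermal_scalars(c(ta, tv, tc, tp, tw), command$hcu_setpoint,
                               command$flow_fraction, p, dt, mf)
    if (any(!is.finite(y)) || any(y < 0) || any(y > 45))
      stop(sprintf(paste0("thermal-state invariant violated at tick %d ",
                          "(t=%.0fs): state = [%s]"), i, t_now,
                   paste(sprintf("%.3f", y), collapse = ", ")))
    ta <- y[1]; tv <- y[2]; tc <- y[3]; tp <- y[4]; tw <- y[5]
  }

  series <- as.data.frame(S, stringsAsFactors = FALSE)
  ev <- if (n_ev > 0) do.call(rbind, events[seq_len(n_ev)])
        else .empty_events()

  compliance <- gradient_compliance(series,
                                    cooling_limit = ctrl$cooling_gradient_max,
                                    rewarming_limit =
                                      ctrl$rewarming_gradient_max)
  at_target <- abs(series$t_core - scen$target_core_temp) <=
    ctrl$stability_band
  time_to_target <- if (any(at_target))
    series$time_s[which(at_target)[1]] / 60 else NA_real_
  overshoot <- max(0, scen$target_core_temp - min(series$t_core))
  counts <- table(factor(ev$kind, levels = names(alarm_kinds)))

  structure(list(series = series, events = ev,
                 metrics = list(gradient_compliance = compliance,
                                time_to_target_min = time_to_target,
                                max_core_overshoot = overshoot,
                                alarm_counts = counts),
                 scenario = scen, seed = scen$seed,
                 config_hash = .config_hash(config)),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<simulation_result '%s'> %d ticks, seed %d\n",
              x$scenario$name, nrow(x$series), x$seed))
  cat(sprintf("  gradient compliance: %.4f\n", m$gradient_compliance))
  cat(sprintf("  time to target:      %s min\n",
              if (is.na(m$time_to_target_min)) "not reached"
              else sprintf("%.1f", m$time_to_target_min)))
  cat(sprintf("  max core overshoot:  %.3f C\n", m$max_core_overshoot))
  nz <- m$alarm_counts[m$alarm_counts > 0]
  cat("  alarms:", if (length(nz))
    paste(names(nz), as.integer(nz), sep = "=", collapse = ", ")
    else "none", "\n")
  invisible(x)
}

#' Fraction of ticks satisfying the phase-conditional gradient constraints
#'
#' During cooling the constraint is blood minus HCU water at or below the
#' cooling limit (10 C); during the rewarming phases, blood minus core at
#' or below the rewarming limit (4 C). Both are evaluated on the true
#' state. The fraction is taken over the constrained ticks (ticks in
#' phases where a constraint applies); a run with no constrained ticks is
#' vacuously compliant (1.0).
#'
#' @param x a `simulation_result` or its `series` data frame (e.g. read
#'   back by [read_timeseries()]).
#' @param cooling_limit,rewarming_limit gradient limits, C.
#' @return Compliance fraction in `[0, 1]`.
#' @export
gradient_compliance <- function(x, cooling_limit = 10, rewarming_limit = 4) {
  series <- if (inherits(x, "simulation_result")) x$series else x
  if (!is.data.frame(series) || nrow(series) == 0)
    stop("gradient_compliance requires a non-empty tick series")
  eps <- 1e-9
  cooling <- series$phase == "COOLING"
  rewarming <- series$phase %in% c("REWARMING", "FINAL_REWARMING")
  ok <- rep(TRUE, nrow(series))
  ok[cooling] <- (series$t_arterial - series$t_hcu_water)[cooling] <=
    cooling_limit + eps
  ok[rewarming] <- (series$t_arterial - series$t_core)[rewarming] <=
    rewarming_limit + eps
  constrained <- cooling | rewarming
  if (!any(constrained)) return(1)
  mean(ok[constrained])
}

#' Monte-Carlo sensor-dropout study
#'
#' Runs the scenario `n_runs` times under the sensing module's dropout
#' model with seeds `base_seed .. base_seed + n_runs - 1` and summarises
#' gradient compliance and alarm counts across runs. With `n_runs = 1`
#' this reproduces [run_scenario()] exactly.
#'
#' @param n_runs number of seeded runs (>= 1).
#' @param scen a [scenario()].
#' @param config a [sim_config()].
#' @param base_seed first seed.
#' @return An object of class `dropout_study`: list with `runs` (per-run
#'   data frame), `mean_compliance`, `min_compliance`,
#'   `compliance_quantiles`, `alarm_counts` (summed across runs),
#'   `n_runs`, `base_seed`.
#' @export
dropout_study <- function(n_runs, scen = scenario(),
                          config = sim_config(), base_seed = 20250915) {
  stopifnot(n_runs >= 1)
  comp <- numeric(n_runs)
  ttt <- numeric(n_runs)
  counts <- stats::setNames(integer(length(alarm_kinds)),
                            names(alarm_kinds))
  seeds <- base_seed + seq_len(n_runs) - 1
  for (j in seq_len(n_runs)) {
    sj <- scen
    sj$seed <- as.integer(seeds[j])
    res <- run_scenario(sj, config)
    comp[j] <- res$metrics$gradient_compliance
    ttt[j] <- res$metrics$time_to_target_min
    counts <- counts + as.integer(res$metrics$alarm_counts)
  }
  structure(list(runs = data.frame(seed = seeds, compliance = comp,
                                   time_to_target_min = ttt),
                 mean_compliance = mean(comp),
                 min_compliance = min(comp),
                 compliance_quantiles =
                   stats::quantile(comp, c(0.05, 0.25, 0.5, 0.75, 0.95)),
                 alarm_counts = counts,
                 n_runs = n_runs, base_seed = base_seed),
            class = "dropout_study")
}

#' @export
print.dropout_study <- function(x, ...) {
  cat(sprintf("<dropout_study> %d runs, base seed %d\n", x$n_runs,
              x$base_seed))
  cat(sprintf("  mean compliance: %.4f  (min %.4f)\n", x$mean_compliance,
              x$min_compliance))
  print(round(x$compliance_quantiles, 4))
  nz <- x$alarm_counts[x$alarm_counts > 0]
  cat("  alarms:", if (length(nz))
    paste(names(nz), as.integer(nz), sep = "=", collapse = ", ")
    else "none", "\n")
  invisible(x)
}

#' Write the tick-level time series to CSV
#'
#' Writes the standard audit columns (`time_s`, the five true
#' temperatures, `fused_core`, `hcu_setpoint`, `flow_fraction`,
#' `do2_floor`, `phase`, `ph_strategy`), numerics rounded to 6 decimals.
#'
#' @param result a `simulation_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(result, path) {
  series <- if (inherits(result, "simulation_result")) result$series
            else result
  df <- series[, .timeseries_columns]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 6)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a time-series CSV written by [write_timeseries()]
#'
#' Validates the header and column types; a malformed header or row is
#' rejected with the offending line number.
#'
#' @param path CSV path.
#' @return The tick-level data frame.
#' @export
read_timeseries <- function(path) {
  header <- strsplit(readLines(path, n = 1), ",", fixed = TRUE)[[1]]
  if (!identical(header, .timeseries_columns))
    stop("malformed time-series header (line 1): expected [",
         paste(.timeseries_columns, collapse = ", "), "], got [",
         paste(header, collapse = ", "), "]")
  nf <- utils::count.fields(path, sep = ",")
  bad <- which(nf != length(.timeseries_columns))
  if (length(bad))
    stop("malformed time-series row at line ", bad[1],
         ": expected ", length(.timeseries_columns), " fields, found ",
         nf[bad[1]])
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rep("numeric", 10),
                                       "character", "character"))
  num_cols <- .timeseries_columns[1:10]
  for (cc in num_cols) {
    nas <- which(!is.finite(df[[cc]]) & df$phase != "")
    # fused_core may legitimately be NA during total core-sensing loss
    if (cc != "fused_core" && length(nas))
      stop("non-numeric value in column '", cc, "' at line ", nas[1] + 1)
  }
  if (!all(df$phase %in% controller_phases))
    stop("unknown phase label at line ",
         which(!df$phase %in% controller_phases)[1] + 1)
  df
}

#' Recompute gradient compliance from a time-series CSV
#'
#' Audit mode: the compliance metric recomputed from a written CSV equals
#' the in-run metric (single source of truth).
#'
#' @param path CSV path from [write_timeseries()].
#' @inheritParams gradient_compliance
#' @return Compliance fraction.
#' @export
audit_timeseries <- function(path, cooling_limit = 10, rewarming_limit = 4) {
  gradient_compliance(read_timeseries(path), cooling_limit = cooling_limit,
                      rewarming_limit = rewarming_limit)
}
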
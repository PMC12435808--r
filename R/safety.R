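#' Alarm kinds and severities
#'
#' The closed set of alarm kinds raised by the fail-safe layer, with their
#' default severities. Gradient and absolute-bound breaches are critical;
#' rate, sensing, oxygen-delivery and cerebral-saturation alarms are
#' warnings; `override` records manual interventions for the audit trail.
#' @export
alarm_kinds <- c(gradient_breach = "critical",
                 rate_breach = "warning",
                 temp_bound = "critical",
                 rewarm_rate = "warning",
                 sensor_loss = "warning",
                 do2_deficit = "warning",
                 rso2_low = "warning",
                 override = "advisory")

#' Safety (alarm-engine) configuration
#'
#' Debounce and hysteresis are the concrete mitigation for alarm fatigue:
#' a condition must persist `debounce_ticks` consecutive ticks before an
#' event fires, and must then stay clear for `hysteresis_ticks` before the
#' same kind can fire again.
#'
#' @param debounce_ticks consecutive ticks a condition must persist before
#'   firing.
#' @param hysteresis_ticks consecutive clear ticks required to re-arm.
#' @param rso2_baseline baseline regional cerebral oxygen saturation, %.
#' @param rso2_relative_drop relative drop below baseline that triggers
#'   `rso2_low` (default 20%).
#' @param rewarm_rate_limit maximum measured core rise, C, over
#'   `rewarm_rate_window_s` during rewarming.
#' @param rewarm_rate_window_s window for the measured-rate check, s.
#' @param bound_margin_c nuisance margin on the absolute temperature
#'   bounds: `temp_bound` fires only beyond
#'   `[temp_min - margin, temp_max + margin]`. A patient starting at 37 C
#'   inevitably drifts about a tenth of a degree above 37 before the
#'   water setpoint pulls away (metabolic heat with no water-blood
#'   gradient yet to remove it); the margin keeps that transient from
#'   raising a critical alarm while still catching real bound violations.
#' @return An object of class `safety_config`.
#' @export
safety_config <- function(debounce_ticks = 3,
                          hysteresis_ticks = 10,
                          rso2_baseline = 65,
                          rso2_relative_drop = 0.20,
                          rewarm_rate_limit = 1,
                          rewarm_rate_window_s = 180,
                          bound_margin_c = 0.2) {
  stopifnot(debounce_ticks >= 1, hysteresis_ticks >= 0,
            rso2_baseline > 0, rso2_relative_drop > 0,
            rso2_relative_drop < 1,
            rewarm_rate_limit > 0, rewarm_rate_window_s > 0,
            bound_margin_c >= 0)
  structure(list(debounce_ticks = as.integer(debounce_ticks),
                 hysteresis_ticks = as.integer(hysteresis_ticks),
                 rso2_baseline = rso2_baseline,
                 rso2_relative_drop = rso2_relative_drop,
                 rewarm_rate_limit = rewarm_rate_limit,
                 rewarm_rate_window_s = rewarm_rate_window_s,
                 bound_margin_c = bound_margin_c),
            class = "safety_config")
}

#' Create an alarm-engine state
#'
#' The engine tracks, per alarm kind, the current condition streak, the
#' clear streak, and whether the kind is armed. It is advanced one tick at
#' a time by [check_alarms()].
#'
#' @param safety a [safety_config()].
#' @return An object of class `alarm_engine`.
#' @export
alarm_engine <- function(safety = safety_config()) {
  k <- names(alarm_kinds)
  structure(list(streak = stats::setNames(integer(length(k)), k),
                 clear = stats::setNames(integer(length(k)), k),
                 armed = stats::setNames(rep(TRUE, length(k)), k),
                 safety = safety),
            class = "alarm_engine")
}

.empty_events <- function() {
  data.frame(kind = character(), severity = character(), time = numeric(),
             message = character(), acknowledged = logical(),
             stringsAsFactors = FALSE)
}

# advance the engine one tick given named logical conditions; returns
# list(engine, fired = character vector of kinds)
.alarm_engine_step <- function(engine, conds) {
  fired <- character()
  deb <- engine$safety$debounce_ticks
  hys <- engine$safety$hysteresis_ticks
  for (k in names(alarm_kinds)) {
    on <- isTRUE(conds[[k]])
    if (on) {
      engine$streak[[k]] <- engine$streak[[k]] + 1L
      engine$clear[[k]] <- 0L
      if (engine$armed[[k]] && engine$streak[[k]] >= deb) {
        fired <- c(fired, k)
        engine$armed[[k]] <- FALSE
      }
    } else {
      engine$streak[[k]] <- 0L
      engine$clear[[k]] <- engine$clear[[k]] + 1L
      if (!engine$armed[[k]] && engine$clear[[k]] >= hys)
        engine$armed[[k]] <- TRUE
    }
  }
  list(engine = engine, fired = fired)
}

# evaluate alarm conditions for one tick. state is the TRUE thermal state
# (gradient completeness is checked against ground truth); context supplies
# the derived channels.
.alarm_conditions <- function(state, fused, command, config, safety,
                              context) {
  eps <- 1e-9
  phase <- command$phase
  cooling <- phase == "COOLING"
  rewarming <- phase %in% c("REWARMING", "FINAL_REWARMING")
  grad <- (cooling &&
             state$t_arterial - state$t_hcu_water >
               config$cooling_gradient_max + eps) ||
          (rewarming &&
             state$t_arterial - state$t_core >
               config$rewarming_gradient_max + eps)
  rate_br <- !is.null(context$traj_change) &&
    is.finite(context$traj_change) &&
    abs(context$traj_change) > safety$rewarm_rate_limit + eps
  tb_vals <- c(state$t_arterial, state$t_core)
  mar <- safety$bound_margin_c
  bound <- any(tb_vals < config$temp_min - mar - eps) ||
           any(tb_vals > config$temp_max + mar + eps)
  rw_rate <- rewarming && !is.null(context$core_rise) &&
    is.finite(context$core_rise) &&
    context$core_rise > safety$rewarm_rate_limit + eps
  sloss <- !isTRUE(fused$available) || isTRUE(fused$degraded)
  do2_def <- !is.null(context$do2_delivered) &&
    is.finite(context$do2_delivered) &&
    context$do2_delivered < command$do2_floor - eps
  rso2 <- !is.null(context$rso2) && is.finite(context$rso2) &&
    context$rso2 < safety$rso2_baseline * (1 - safety$rso2_relative_drop)
  list(gradient_breach = grad, rate_breach = rate_br, temp_bound = bound,
       rewarm_rate = rw_rate, sensor_loss = sloss, do2_deficit = do2_def,
       rso2_low = rso2)
}

#' Check alarm conditions for one tick
#'
#' Evaluates all alarm conditions against the true thermal state, the
#' fused estimate and the current command, advances the debounce /
#' hysteresis engine, and returns any events that fire this tick. The
#' engine never throws; malformed context (non-list, missing state) yields
#' a critical `sensor_loss` event instead.
#'
#' @param state the true [thermal_state()].
#' @param fused fused estimate from [fuse_panel()].
#' @param command the current [controller_command()].
#' @param config a [controller_config()].
#' @param safety a [safety_config()].
#' @param engine an [alarm_engine()] (created if `NULL`).
#' @param context list of derived channels: `traj_change` (commanded
#'   trajectory change over the rate window, C), `core_rise` (measured
#'   core rise over the window, C), `do2_delivered` (mL O2/min/m2),
#'   `rso2` (%).
#' @return List with `events` (data frame `kind`, `severity`, `time`,
#'   `message`, `acknowledged`) and the advanced `engine`.
#' @export
check_alarms <- function(state, fused, command, config,
                         safety = safety_config(), engine = NULL,
                         context = list()) {
  if (is.null(engine)) engine <- alarm_engine(safety)
  res <- tryCatch({
    conds <- .alarm_conditions(state, fused, command, config, safety,
                               context)
    stp <- .alarm_engine_step(engine, conds)
    time <- state$time
    ev <- if (length(stp$fired)) {
      data.frame(kind = stp$fired,
                 severity = unname(alarm_kinds[stp$fired]),
                 time = time,
                 message = vapply(stp$fired, function(k)
                   sprintf("%s at t=%.0fs (phase %s)", k, time,
                           command$phase), character(1)),
                 acknowledged = FALSE, stringsAsFactors = FALSE)
    } else .empty_events()
    list(events = ev, engine = stp$engine)
  }, error = function(e) {
    ev <- data.frame(kind = "sensor_loss", severity = "critical",
                     time = if (is.numeric(state$time)) state$time else NA_real_,
                     message = paste("malformed alarm context:",
                                     conditionMessage(e)),
                     acknowledged = FALSE, stringsAsFactors = FALSE)
    list(events = ev, engine = engine)
  })
  res
}

#' Manual override command
#'
#' At least one of the manual setpoint or the forced phase must be given.
#'
#' @param manual_hcu_setpoint C, or `NULL`.
#' @param force_phase one of [controller_phases], or `NULL`.
#' @param issued_by free-text identity of the operator.
#' @param time s.
#' @return An object of class `override_command`.
#' @export
override_command <- function(manual_hcu_setpoint = NULL, force_phase = NULL,
                             issued_by = "perfusionist", time = 0) {
  if (is.null(manual_hcu_setpoint) && is.null(force_phase))
    stop("an override must set a manual setpoint or force a phase")
  if (!is.null(force_phase) && !force_phase %in% controller_phases)
    stop("unknown phase: ", force_phase)
  structure(list(manual_hcu_setpoint = manual_hcu_setpoint,
                 force_phase = force_phase, issued_by = issued_by,
                 time = time),
            class = "override_command")
}

#' Apply a manual override to a controller command
#'
#' A manual setpoint replaces the automated one verbatim but is still
#' clamped to the absolute bounds `[temp_min, temp_max]`; an in-bounds
#' manual setpoint is logged advisory, an out-of-bounds one is clamped and
#' logged warning. A forced phase bypasses the state-machine legality
#' table and is logged critical.
#'
#' @param override an [override_command()].
#' @param command a [controller_command()].
#' @param config a [controller_config()].
#' @return The modified command, with the logged events in attribute
#'   `"events"`.
#' @export
apply_override <- function(override, command, config) {
  events <- .empty_events()
  if (!is.null(override$manual_hcu_setpoint)) {
    sp <- override$manual_hcu_setpoint
    clamped <- min(max(sp, config$temp_min), config$temp_max)
    command$hcu_setpoint <- clamped
    msg <- sprintf("manual setpoint %.2f C by %s", sp, override$issued_by)
    events <- rbind(events, data.frame(
      kind = "override",
      severity = if (clamped != sp) "warning" else "advisory",
      time = override$time,
      message = if (clamped != sp)
        paste(msg, sprintf("(clamped to %.2f C)", clamped)) else msg,
      acknowledged = FALSE, stringsAsFactors = FALSE))
  }
  if (!is.null(override$force_phase)) {
    command$phase <- override$force_phase
    events <- rbind(events, data.frame(
      kind = "override", severity = "critical", time = override$time,
      message = sprintf("phase forced to %s by %s", override$force_phase,
                        override$issued_by),
      acknowledged = FALSE, stringsAsFactors = FALSE))
  }
  attr(command, "events") <- events
  command
}

#' Write alarm events as a JSON-lines audit log
#'
#' One JSON object per line with stable field order (`kind`, `severity`,
#' `time`, `message`, `acknowledged`). Events must be time-ordered; an
#' out-of-order log is rejected (auditability contract). Round-trips
#' losslessly through [read_audit_log()].
#'
#' @param events event data frame as produced by [check_alarms()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(events, path) {
  if (nrow(events) > 0 && is.unsorted(events$time))
    stop("events must be time-ordered for the audit log")
  lines <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    lines[i] <- jsonlite::toJSON(
      list(kind = events$kind[i], severity = events$severity[i],
           time = events$time[i], message = events$message[i],
           acknowledged = events$acknowledged[i]),
      auto_unbox = TRUE, digits = NA)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a JSON-lines audit log
#'
#' @param path file written by [write_audit_log()].
#' @return Event data frame.
#' @export
read_audit_log <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(.empty_events())
  rows <- lapply(lines, function(l) {
    x <- jsonlite::fromJSON(l)
    data.frame(kind = x$kind, severity = x$severity, time = x$time,
               message = x$message, acknowledged = x$acknowledged,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
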
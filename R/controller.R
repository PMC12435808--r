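#' Controller phases
#'
#' The phase state machine of the temperature-management protocol, in
#' protocol order: standby, cooling, hypothermic maintenance, controlled
#' rewarming (up to 32 C), final rewarming (32 C to normothermia), and
#' weaning. Legal transitions follow this order; any phase may return to
#' `STANDBY` only through a manual override.
#' @export
controller_phases <- c("STANDBY", "COOLING", "MAINTENANCE", "REWARMING",
                       "FINAL_REWARMING", "WEANING")

#' Controller configuration
#'
#' Setpoints, safety limits and servo gains of the temperature controller.
#' The hard limits encode standard bypass practice: a maximum 10 C
#' blood-to-HCU-water gradient during cooling, a maximum 4 C blood-to-core
#' gradient during rewarming, a 1 C per 3-5 min rate ceiling on the
#' commanded trajectory (default 1 C per 4 min; values outside 3-5 min per
#' degree are rejected), a slower 1 C per 5 min during final rewarming,
#' and absolute water-setpoint bounds of 18 C (deep hypothermic circulatory
#' arrest floor) and 37 C (hyperthermia ceiling).
#'
#' The HCU setpoint is servoed around the rate-limited core-temperature
#' trajectory with proportional and integral action (`proportional_gain`,
#' `integral_gain`), then clamped by the gradient and absolute limits.
#'
#' @param target_core_temp target core temperature, C (within
#'   `[temp_min, temp_max]`).
#' @param cooling_gradient_max maximum blood minus HCU-water difference
#'   during cooling, C.
#' @param rewarming_gradient_max maximum blood minus core difference during
#'   rewarming, C.
#' @param cooling_rate_min_per_degc minutes per degree for the commanded
#'   trajectory during cooling/rewarming; must lie in `[3, 5]`.
#' @param final_rewarming_rate_min_per_degc minutes per degree during final
#'   rewarming and weaning.
#' @param temp_min,temp_max absolute setpoint bounds, C.
#' @param cooling_activation_threshold targets below this are treated as
#'   hypothermic management; targets at or above it use the same machinery
#'   as tepid management (single code path).
#' @param rewarming_stage_temp core temperature at which controlled
#'   rewarming hands over to final rewarming, C.
#' @param weaning_target core temperature goal for weaning, C.
#' @param weaning_range length-2 band the core must hold before weaning, C.
#' @param stability_band half-width of the target band that ends cooling, C.
#' @param stability_window_min minutes the core must stay in
#'   `weaning_range` (with DO2 met) before weaning.
#' @param proportional_gain,integral_gain servo gains (dimensionless; per
#'   second).
#' @param integral_limit cap on the integral term's setpoint authority, C.
#' @param standard_cardiac_index full pump flow, L/min/m2.
#' @param minimum_valid_core_sensors passed to [fuse_panel()].
#' @return An object of class `controller_config`.
#' @export
controller_config <- function(target_core_temp = 20,
                              cooling_gradient_max = 10,
                              rewarming_gradient_max = 4,
                              cooling_rate_min_per_degc = 4,
                              final_rewarming_rate_min_per_degc = 5,
                              temp_min = 18,
                              temp_max = 37,
                              cooling_activation_threshold = 32,
                              rewarming_stage_temp = 32,
                              weaning_target = 36.5,
                              weaning_range = c(36, 37),
                              stability_band = 0.2,
                              stability_window_min = 5,
                              proportional_gain = 3,
                              integral_gain = 1 / 240,
                              integral_limit = 5,
                              standard_cardiac_index = 2.4,
                              minimum_valid_core_sensors = 2) {
  if (!is.finite(target_core_temp) ||
      target_core_temp < temp_min || target_core_temp > temp_max)
    stop("target_core_temp must lie within [temp_min, temp_max]")
  if (cooling_gradient_max <= 0 || rewarming_gradient_max <= 0)
    stop("gradient limits must be strictly positive")
  if (cooling_rate_min_per_degc < 3 || cooling_rate_min_per_degc > 5)
    stop("cooling_rate_min_per_degc must lie in [3, 5] minutes per degree")
  if (final_rewarming_rate_min_per_degc <= 0)
    stop("final rewarming rate must be strictly positive")
  stopifnot(length(weaning_range) == 2, weaning_range[1] < weaning_range[2],
            stability_band > 0, stability_window_min > 0)
  structure(list(target_core_temp = target_core_temp,
                 cooling_gradient_max = cooling_gradient_max,
                 rewarming_gradient_max = rewarming_gradient_max,
                 cooling_rate_min_per_degc = cooling_rate_min_per_degc,
                 final_rewarming_rate_min_per_degc =
                   final_rewarming_rate_min_per_degc,
                 temp_min = temp_min, temp_max = temp_max,
                 cooling_activation_threshold = cooling_activation_threshold,
                 rewarming_stage_temp = rewarming_stage_temp,
                 weaning_target = weaning_target,
                 weaning_range = as.numeric(weaning_range),
                 stability_band = stability_band,
                 stability_window_min = stability_window_min,
                 proportional_gain = proportional_gain,
                 integral_gain = integral_gain,
                 integral_limit = integral_limit,
                 standard_cardiac_index = standard_cardiac_index,
                 minimum_valid_core_sensors = minimum_valid_core_sensors),
            class = "controller_config")
}

#' Controller command
#'
#' What the controller emits each tick: the HCU water setpoint, the pump
#' flow fraction (1 = standard flow), the DO2 floor in force, the pH and
#' CO2 strategies, the phase, the internal rate-limited trajectory target
#' and servo integral, and a `hold` flag set when the command is a
#' held-last-safe copy emitted during total sensing loss.
#'
#' @param hcu_setpoint C (finite).
#' @param flow_fraction fraction of standard flow, in `[0, 1.2]`.
#' @param do2_floor mL O2/min/m2.
#' @param ph_strategy,co2_strategy policy labels.
#' @param phase one of [controller_phases].
#' @param traj_target rate-limited core trajectory target, C.
#' @param integral servo integral state, C s.
#' @param hold logical fail-safe flag.
#' @return An object of class `controller_command`.
#' @export
controller_command <- function(hcu_setpoint, flow_fraction = 1,
                               do2_floor = 286,
                               ph_strategy = "alpha-stat",
                               co2_strategy = "standard CO2 removal",
                               phase = "STANDBY",
                               traj_target = hcu_setpoint,
                               integral = 0, hold = FALSE) {
  if (!is.finite(hcu_setpoint)) stop("hcu_setpoint must be finite")
  if (!is.finite(flow_fraction) || flow_fraction < 0 || flow_fraction > 1.2)
    stop("flow_fraction must lie in [0, 1.2]")
  if (!phase %in% controller_phases) stop("unknown phase: ", phase)
  structure(list(hcu_setpoint = hcu_setpoint, flow_fraction = flow_fraction,
                 do2_floor = do2_floor, ph_strategy = ph_strategy,
                 co2_strategy = co2_strategy, phase = phase,
                 traj_target = traj_target, integral = integral,
                 hold = hold),
            class = "controller_command")
}

#' @export
print.controller_command <- function(x, ...) {
  cat(sprintf(paste0("<controller_command %s> setpoint %.2f C | flow %.2f",
                     " | DO2 floor %.0f | %s | %s%s\n"),
              x$phase, x$hcu_setpoint, x$flow_fraction, x$do2_floor,
              x$ph_strategy, x$co2_strategy,
              if (x$hold) " | HOLD" else ""))
  invisible(x)
}

#' Phase transition
#'
#' One step of the phase state machine. Cooling ends when the fused core
#' estimate enters the stability band around the target; maintenance hands
#' over to rewarming only once the surgical team permits; controlled
#' rewarming becomes final rewarming at the staging temperature (32 C);
#' final rewarming becomes weaning once [weaning_ready()] reports a
#' sustained normothermic window. A forced phase in `flags$override`
#' bypasses the legality table (the safety module logs it as critical).
#' When the fused estimate is unavailable the phase is held unchanged; the
#' accompanying sensor-loss alarm is the safety module's responsibility.
#'
#' @param phase current phase, one of [controller_phases].
#' @param fused fused estimate from [fuse_panel()].
#' @param config a [controller_config()].
#' @param flags list with logicals `rewarm_permitted`, `weaning_ready`, and
#'   optionally `override` (a phase name).
#' @return The next phase.
#' @export
transition <- function(phase, fused, config, flags = list()) {
  if (!is.null(flags$override)) return(flags$override)
  if (!isTRUE(fused$available)) return(phase)
  core <- fused$core
  switch(phase,
    STANDBY = if (core > config$target_core_temp + config$stability_band)
      "COOLING" else "STANDBY",
    COOLING = if (abs(core - config$target_core_temp) <=
                  config$stability_band) "MAINTENANCE" else "COOLING",
    MAINTENANCE = if (isTRUE(flags$rewarm_permitted)) "REWARMING"
      else "MAINTENANCE",
    REWARMING = if (core >= config$rewarming_stage_temp) "FINAL_REWARMING"
      else "REWARMING",
    FINAL_REWARMING = if (isTRUE(flags$weaning_ready)) "WEANING"
      else "FINAL_REWARMING",
    WEANING = "WEANING",
    stop("unknown phase: ", phase))
}

#' Rate-limited trajectory target
#'
#' Moves the previous trajectory target toward the goal by at most
#' `rate * dt`, never overshooting the goal. This is the ceiling on how
#' fast the controller is allowed to demand temperature change.
#'
#' @param prev_target previous target, C.
#' @param goal goal temperature, C.
#' @param dt step, s.
#' @param rate_c_per_min maximum rate, C per minute (> 0).
#' @return The new trajectory target, C.
#' @export
#' @examples
#' rate_limited_target(37, 28, dt = 60, rate_c_per_min = 0.25)
rate_limited_target <- function(prev_target, goal, dt, rate_c_per_min) {
  if (rate_c_per_min <= 0) stop("rate must be > 0")
  step <- rate_c_per_min * dt / 60
  prev_target + max(-step, min(step, goal - prev_target))
}

# per-phase trajectory goal and rate (C/min); STANDBY holds the target
# through the same servo path (tepid management shares the machinery)
.phase_goal_rate <- function(phase, config) {
  switch(phase,
    STANDBY = ,
    COOLING = ,
    MAINTENANCE = list(goal = config$target_core_temp,
                       rate = 1 / config$cooling_rate_min_per_degc),
    REWARMING = list(goal = config$weaning_target,
                     rate = 1 / config$cooling_rate_min_per_degc),
    FINAL_REWARMING = ,
    WEANING = list(goal = config$weaning_target,
                   rate = 1 / config$final_rewarming_rate_min_per_degc),
    NULL)
}

#' Compute the controller command for one tick
#'
#' The commanded core trajectory is advanced toward the phase goal under
#' the rate ceiling (in `STANDBY` the goal is simply the target, so a
#' normothermic target idles as an active hold through the same code
#' path); the HCU setpoint is servoed around it
#' (proportional-integral on the fused core error) and then clamped:
#' during cooling and maintenance the setpoint may not fall more than
#' `cooling_gradient_max` below the fused blood temperature (10 C
#' blood-water rule); during the rewarming phases it may not rise more
#' than `rewarming_gradient_max` above the fused core temperature — since
#' arterial blood in the thermal model is always a convex combination of
#' water and tissue temperatures, bounding the water by core + 4 C bounds
#' every reachable blood temperature, enforcing the 4 C blood-core rule by
#' construction. Finally the setpoint is clamped to
#' `[temp_min, temp_max]`. Flow fraction, DO2 floor and the pH/CO2
#' strategies come from the policy table at the fused core estimate.
#'
#' If the fused estimate is unavailable, the previous command is re-emitted
#' unchanged with `hold = TRUE` (hold-last-safe-command contract).
#'
#' @param phase current phase.
#' @param fused fused estimate from [fuse_panel()].
#' @param config a [controller_config()].
#' @param prev previous [controller_command()].
#' @param policy a [policy_table()].
#' @param dt tick length, s.
#' @return A `controller_command`.
#' @export
compute_command <- function(phase, fused, config, prev, policy, dt = 1) {
  if (!isTRUE(fused$available)) {
    prev$hold <- TRUE
    prev$phase <- phase
    return(prev)
  }
  core <- fused$core
  blood <- fused$blood
  # policy tables are defined on the anchor range; clamp the lookup
  # temperature so sensor noise or the start-of-bypass drift just above
  # 37 C holds the nearest anchor without warning chatter
  rng <- range(policy$anchors_c)
  tpol <- min(max(core, rng[1]), rng[2])
  gr <- .phase_goal_rate(phase, config)
  traj <- rate_limited_target(prev$traj_target, gr$goal, dt, gr$rate)
  err <- traj - core
  integral <- prev$integral
  raw <- traj + config$proportional_gain * err +
    config$integral_gain * integral
  lo <- config$temp_min
  hi <- config$temp_max
  if (phase %in% c("STANDBY", "COOLING", "MAINTENANCE"))
    lo <- max(lo, blood - config$cooling_gradient_max)
  if (phase %in% c("REWARMING", "FINAL_REWARMING", "WEANING"))
    hi <- min(hi, core + config$rewarming_gradient_max)
  if (lo > hi) hi <- lo  # degenerate: prefer the cooler (safer) bound
  setp <- min(max(raw, lo), hi)
  # anti-windup: integrate only while the raw servo output is unsaturated
  if (raw > lo && raw < hi) {
    integral <- integral + err * dt
    cap <- config$integral_limit / max(config$integral_gain, 1e-12)
    integral <- min(max(integral, -cap), cap)
  }
  flow <- min(max(1 - flow_reduction(tpol, policy), 0), 1.2)
  controller_command(
    hcu_setpoint = setp, flow_fraction = flow,
    do2_floor = do2_target(tpol, policy),
    ph_strategy = ph_strategy(tpol, policy),
    co2_strategy = co2_strategy(tpol, policy),
    phase = phase, traj_target = traj, integral = integral, hold = FALSE)
}

#' Readiness to wean from bypass
#'
#' `TRUE` iff the fused core estimate has remained inside the weaning
#' band (default `[36, 37]` C) and the DO2 floor has been met for every
#' sample in the most recent stability window. Insufficient history yields
#' `FALSE`, not an error.
#'
#' @param core_history numeric vector of fused core estimates, oldest
#'   first, sampled every `dt` seconds.
#' @param do2_met logical vector parallel to `core_history` (delivered DO2
#'   at or above the floor).
#' @param config a [controller_config()].
#' @param dt sample spacing, s.
#' @return Logical.
#' @export
weaning_ready <- function(core_history, do2_met, config, dt = 1) {
  n_need <- ceiling(config$stability_window_min * 60 / dt)
  n <- length(core_history)
  if (n < n_need) return(FALSE)
  idx <- (n - n_need + 1L):n
  win <- core_history[idx]
  all(is.finite(win)) &&
    all(win >= config$weaning_range[1]) &&
    all(win <= config$weaning_range[2]) &&
    all(do2_met[idx])
}
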
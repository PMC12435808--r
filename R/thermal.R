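#' Patient thermal parameters
#'
#' Parameters of the lumped-compartment heat-exchange model: four
#' compartments (arterial blood, venous blood, core, peripheral) plus the
#' heater-cooler unit (HCU) water temperature as a first-order actuator.
#' Heat enters arterial blood through the oxygenator heat exchanger at
#' `effectiveness * hx_conductance * flow_fraction * (T_water - T_venous)`;
#' arterial and venous blood exchange through a circulatory mixing
#' conductance, venous blood exchanges with the core, and the core with the
#' peripheral compartment, all linearly in the temperature differences.
#' Metabolic heat, scaled by [metabolic_fraction()] of the core
#' temperature, is deposited in the core.
#'
#' Defaults describe a 70 kg adult (BSA 1.8 m2): 5 L blood split 30/70
#' arterial/venous, 40 kg core, 25 kg peripheral shell, tissue specific
#' heat 3.5 kJ/kg/C, blood 3.6 kJ/kg/C. Conductances are tuned so that an
#' unconstrained HCU at the maximum 10 C blood-water gradient cools the
#' body at roughly 1 C per 2.5-3 min at operating flows, while rewarming
#' at the 4 C blood-core gradient proceeds at a clinically typical
#' 6-9 min per degree.
#'
#' @param blood_volume_l total blood volume, L (1 kg/L assumed).
#' @param arterial_fraction fraction of blood volume in the arterial
#'   compartment.
#' @param core_mass_kg,peripheral_mass_kg compartment masses, kg.
#' @param blood_specific_heat,tissue_specific_heat J/kg/C.
#' @param hx_conductance heat-exchanger conductance at full flow, W/C.
#' @param hx_effectiveness heat-exchanger effectiveness, in `(0, 1]`.
#' @param circulatory_conductance arterial-venous mixing conductance, W/C.
#' @param core_blood_conductance venous blood to core conductance, W/C.
#' @param core_peripheral_conductance core to peripheral conductance, W/C.
#' @param hcu_time_constant first-order lag of HCU water behind its
#'   setpoint, s (0 = instantaneous).
#' @param body_surface_area m2.
#' @param baseline_metabolic_rate whole-body metabolic heat at 37 C, W.
#' @param baseline_vo2 oxygen consumption at 37 C, mL O2/min/m2.
#' @return An object of class `patient_params`.
#' @export
patient_params <- function(blood_volume_l = 5,
                           arterial_fraction = 0.3,
                           core_mass_kg = 40,
                           peripheral_mass_kg = 25,
                           blood_specific_heat = 3600,
                           tissue_specific_heat = 3500,
                           hx_conductance = 700,
                           hx_effectiveness = 0.75,
                           circulatory_conductance = 600,
                           core_blood_conductance = 450,
                           core_peripheral_conductance = 120,
                           hcu_time_constant = 30,
                           body_surface_area = 1.8,
                           baseline_metabolic_rate = 72,
                           baseline_vo2 = 120) {
  p <- list(
    c_arterial = blood_volume_l * arterial_fraction * blood_specific_heat,
    c_venous = blood_volume_l * (1 - arterial_fraction) * blood_specific_heat,
    c_core = core_mass_kg * tissue_specific_heat,
    c_peripheral = peripheral_mass_kg * tissue_specific_heat,
    g_hx = hx_conductance,
    hx_effectiveness = hx_effectiveness,
    g_circ = circulatory_conductance,
    g_core = core_blood_conductance,
    g_peripheral = core_peripheral_conductance,
    hcu_time_constant = hcu_time_constant,
    body_surface_area = body_surface_area,
    baseline_metabolic_rate = baseline_metabolic_rate,
    baseline_vo2 = baseline_vo2)
  caps <- c(p$c_arterial, p$c_venous, p$c_core, p$c_peripheral)
  if (any(!is.finite(caps)) || any(caps <= 0))
    stop("all compartment heat capacities must be strictly positive")
  conds <- c(p$g_hx, p$g_circ, p$g_core, p$g_peripheral)
  if (any(!is.finite(conds)) || any(conds <= 0))
    stop("all conductances must be strictly positive")
  if (!is.finite(p$hx_effectiveness) ||
      p$hx_effectiveness <= 0 || p$hx_effectiveness > 1)
    stop("hx_effectiveness must lie in (0, 1]")
  if (p$hcu_time_constant < 0) stop("hcu_time_constant must be >= 0")
  if (p$baseline_metabolic_rate < 0) stop("metabolic rate must be >= 0")
  structure(p, class = "patient_params")
}

#' Thermal state of the simulated patient
#'
#' True compartment temperatures plus the HCU water temperature; the
#' simulation ground truth. All temperatures must be finite and within the
#' sanity band `[0, 45]` C.
#'
#' @param t_arterial,t_venous,t_core,t_peripheral,t_hcu_water degrees C.
#' @param time seconds since bypass start (>= 0).
#' @return An object of class `thermal_state`.
#' @export
thermal_state <- function(t_arterial = 37, t_venous = 37, t_core = 37,
                          t_peripheral = 37, t_hcu_water = 37, time = 0) {
  temps <- c(t_arterial, t_venous, t_core, t_peripheral, t_hcu_water)
  if (any(!is.finite(temps)) || any(temps < 0) || any(temps > 45))
    stop("temperatures must be finite and within [0, 45] C")
  if (!is.finite(time) || time < 0) stop("time must be finite and >= 0")
  structure(list(t_arterial = t_arterial, t_venous = t_venous,
                 t_core = t_core, t_peripheral = t_peripheral,
                 t_hcu_water = t_hcu_water, time = time),
            class = "thermal_state")
}

#' @export
print.thermal_state <- function(x, ...) {
  cat(sprintf(paste0("<thermal_state t=%.0fs> art %.2f | ven %.2f | core ",
                     "%.2f | periph %.2f | HCU water %.2f C\n"),
              x$time, x$t_arterial, x$t_venous, x$t_core, x$t_peripheral,
              x$t_hcu_water))
  invisible(x)
}

# scalar Euler step shared by step_thermal() and the simulation loop.
# x = c(ta, tv, tc, tp, tw); returns the advanced vector.
.step_thermal_scalars <- function(x, setpoint, flow, p, dt, met_frac) {
  a <- p$hx_effectiveness * p$g_hx * flow
  q_hx <- a * (x[5] - x[2])
  q_met <- p$baseline_metabolic_rate * met_frac
  ta <- x[1] + dt * (q_hx + p$g_circ * (x[2] - x[1])) / p$c_arterial
  tv <- x[2] + dt * (p$g_circ * (x[1] - x[2]) +
                     p$g_core * (x[3] - x[2])) / p$c_venous
  tc <- x[3] + dt * (p$g_core * (x[2] - x[3]) +
                     p$g_peripheral * (x[4] - x[3]) + q_met) / p$c_core
  tp <- x[4] + dt * p$g_peripheral * (x[3] - x[4]) / p$c_peripheral
  tw <- if (p$hcu_time_constant > 0)
    x[5] + dt * (setpoint - x[5]) / p$hcu_time_constant
  else setpoint
  c(ta, tv, tc, tp, tw)
}

#' Advance the patient thermal model by one time step
#'
#' Explicit-Euler integration of the compartment energy balances under a
#' controller command (HCU water setpoint and pump flow fraction). The HCU
#' water temperature tracks the setpoint with a first-order lag.
#'
#' @param state a [thermal_state()].
#' @param command a list with at least `hcu_setpoint` (C) and
#'   `flow_fraction` (>= 0), e.g. a `controller_command`.
#' @param params a [patient_params()].
#' @param dt time step, s (> 0). Default 1 s.
#' @param policy a [policy_table()] supplying the metabolic temperature
#'   dependence.
#' @return The advanced `thermal_state`.
#' @export
#' @examples
#' st <- thermal_state()
#' step_thermal(st, list(hcu_setpoint = 30, flow_fraction = 1),
#'              patient_params())
step_thermal <- function(state, command, params, dt = 1,
                         policy = default_policy_table()) {
  if (!is.finite(dt) || dt <= 0) stop("dt must be finite and > 0")
  if (!is.finite(command$hcu_setpoint))
    stop("command hcu_setpoint must be finite")
  if (!is.finite(command$flow_fraction) || command$flow_fraction < 0)
    stop("command flow_fraction must be finite and >= 0")
  x <- c(state$t_arterial, state$t_venous, state$t_core,
         state$t_peripheral, state$t_hcu_water)
  if (any(!is.finite(x))) stop("state temperatures must be finite")
  mf <- if (params$baseline_metabolic_rate > 0)
    metabolic_fraction(min(max(state$t_core, 10), 40), policy)
  else 0
  y <- .step_thermal_scalars(x, command$hcu_setpoint,
                             command$flow_fraction, params, dt, mf)
  thermal_state(y[1], y[2], y[3], y[4], y[5], state$time + dt)
}

#' Equilibrium core temperature under a constant HCU setting
#'
#' The fixed point of [step_thermal()] with metabolic heat included: with
#' the HCU water held at `hcu_temp` and the pump at `flow_fraction`, all
#' net fluxes vanish when metabolic heat leaves through the heat exchanger,
#' placing the core `Q/(a) + Q/g_core` above the water temperature (with
#' `a` the flow-scaled effective exchanger conductance). The metabolic heat
#' itself depends on core temperature, so the fixed point is found by
#' functional iteration.
#'
#' @param params a [patient_params()].
#' @param hcu_temp held HCU water temperature, C.
#' @param flow_fraction pump flow as a fraction of standard flow (> 0 when
#'   metabolic heat is nonzero).
#' @param policy a [policy_table()].
#' @return Equilibrium core temperature (C), with the full compartment
#'   vector in attribute `"state"`.
#' @export
equilibrium_temperature <- function(params, hcu_temp, flow_fraction = 1,
                                    policy = default_policy_table()) {
  if (!is.finite(hcu_temp)) stop("hcu_temp must be finite")
  if (params$baseline_metabolic_rate == 0) {
    out <- hcu_temp
    attr(out, "state") <- c(t_arterial = hcu_temp, t_venous = hcu_temp,
                            t_core = hcu_temp, t_peripheral = hcu_temp)
    return(out)
  }
  if (flow_fraction <= 0)
    stop("no finite equilibrium: zero flow with nonzero metabolic heat")
  a <- params$hx_effectiveness * params$g_hx * flow_fraction
  tc <- hcu_temp
  for (i in 1:100) {
    q <- params$baseline_metabolic_rate *
      metabolic_fraction(min(max(tc, 10), 40), policy)
    tv <- hcu_temp + q / a
    tc_new <- tv + q / params$g_core
    if (abs(tc_new - tc) < 1e-10) { tc <- tc_new; break }
    tc <- tc_new
  }
  q <- params$baseline_metabolic_rate *
    metabolic_fraction(min(max(tc, 10), 40), policy)
  tv <- hcu_temp + q / a
  ta <- tv - q / params$g_circ
  out <- tc
  attr(out, "state") <- c(t_arterial = ta, t_venous = tv,
                          t_core = tc, t_peripheral = tc)
  out
}
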
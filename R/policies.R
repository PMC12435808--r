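#' Temperature-indexed perfusion policy table
#'
#' Holds the five-anchor policy used throughout the controller: for each
#' anchor temperature, the fractional metabolic rate reduction, the minimum
#' acceptable indexed oxygen delivery (DO2), the fractional pump-flow
#' reduction, and the blood-gas (pH) and sweep-gas (CO2) strategies.
#' Values between anchors are obtained by piecewise-linear interpolation;
#' outside the anchor range the nearest anchor value is held constant.
#'
#' The default anchors encode standard hypothermic bypass practice:
#' normothermia (37 C), mild (32 C), moderate (28 C) and deep (22 C)
#' hypothermia, and deep hypothermic circulatory arrest (18 C). The 18 C
#' flow row admits two readings (circulatory arrest, or very low flow); the
#' default is very low flow (75% reduction), and a circulatory-arrest
#' interval can be imposed at the scenario level (see [scenario()]).
#'
#' @param anchors_c anchor temperatures in degrees C, strictly decreasing.
#' @param metabolic_reduction fractional reduction of metabolic rate at each
#'   anchor, in `[0, 1]`, strictly increasing as temperature falls.
#' @param do2_min minimum acceptable DO2 at each anchor (mL O2/min/m2),
#'   strictly decreasing as temperature falls.
#' @param flow_reduction fractional reduction of standard pump flow at each
#'   anchor, in `[0, 1]`.
#' @param co2_strategy sweep-gas strategy label at each anchor.
#' @param ph_switch_temp temperature at/below which pH-stat management is
#'   used instead of alpha-stat. Default 28 C with `ph_switch_inclusive =
#'   TRUE` meaning 28 C itself is still alpha-stat; institutions preferring
#'   pH-stat at 28 C set `ph_switch_inclusive = FALSE`.
#' @param ph_switch_inclusive logical; see `ph_switch_temp`.
#' @return An object of class `policy_table`.
#' @export
#' @examples
#' pol <- policy_table()
#' do2_target(30, pol)
policy_table <- function(anchors_c = c(37, 32, 28, 22, 18),
                         metabolic_reduction = c(0, 0.20, 0.50, 0.75, 0.85),
                         do2_min = c(286, 220, 180, 120, 80),
                         flow_reduction = c(0, 0.125, 0.30, 0.50, 0.75),
                         co2_strategy = c("standard CO2 removal",
                                          "moderate CO2 removal",
                                          "adjusted CO2 sweep",
                                          "high CO2 sweep",
                                          "max CO2 sweep"),
                         ph_switch_temp = 28,
                         ph_switch_inclusive = TRUE) {
  n <- length(anchors_c)
  stopifnot(n >= 2,
            length(metabolic_reduction) == n,
            length(do2_min) == n,
            length(flow_reduction) == n,
            length(co2_strategy) == n)
  if (any(!is.finite(anchors_c)))
    stop("policy anchors must be finite temperatures")
  if (any(diff(anchors_c) >= 0))
    stop("policy anchors must be strictly decreasing in temperature")
  if (any(diff(do2_min) >= 0))
    stop("do2_min must strictly decrease as temperature falls")
  if (any(diff(metabolic_reduction) <= 0))
    stop("metabolic_reduction must strictly increase as temperature falls")
  if (any(metabolic_reduction < 0 | metabolic_reduction > 1))
    stop("metabolic_reduction must lie in [0, 1]")
  if (any(flow_reduction < 0 | flow_reduction > 1))
    stop("flow_reduction must lie in [0, 1]")
  if (!is.numeric(ph_switch_temp) || !is.finite(ph_switch_temp))
    stop("ph_switch_temp must be a finite temperature")
  structure(list(anchors_c = as.numeric(anchors_c),
                 metabolic_reduction = as.numeric(metabolic_reduction),
                 do2_min = as.numeric(do2_min),
                 flow_reduction = as.numeric(flow_reduction),
                 co2_strategy = as.character(co2_strategy),
                 ph_switch_temp = ph_switch_temp,
                 ph_switch_inclusive = isTRUE(ph_switch_inclusive)),
            class = "policy_table")
}

#' @export
print.policy_table <- function(x, ...) {
  cat("<policy_table>\n")
  df <- data.frame(temp_c = x$anchors_c,
                   metabolic_reduction = x$metabolic_reduction,
                   do2_min = x$do2_min,
                   flow_reduction = x$flow_reduction,
                   co2_strategy = x$co2_strategy)
  print(df, row.names = FALSE)
  cat(sprintf("pH strategy: alpha-stat %s %.4g C, pH-stat below\n",
              if (x$ph_switch_inclusive) ">=" else ">", x$ph_switch_temp))
  invisible(x)
}

#' Default policy table
#'
#' Convenience wrapper returning [policy_table()] with its default anchors.
#' @return A `policy_table`.
#' @export
default_policy_table <- function() policy_table()

# piecewise-linear interpolation over the anchors, constant beyond the range
.policy_interp <- function(temp, anchors, values) {
  stats::approx(x = rev(anchors), y = rev(values), xout = temp,
                method = "linear", rule = 2)$y
}

#' Metabolic rate as a fraction of the normothermic baseline
#'
#' Returns `1 - reduction` where the reduction is interpolated piecewise
#' linearly between the policy anchors (0% at 37 C down to 85% at 18 C),
#' held constant beyond the anchor range.
#'
#' @param temp temperature(s) in degrees C; must lie in `[10, 40]`.
#' @param table a [policy_table()].
#' @return Fraction(s) of the 37 C metabolic rate, in `(0, 1]`.
#' @export
#' @examples
#' metabolic_fraction(c(37, 28, 18))
metabolic_fraction <- function(temp, table = default_policy_table()) {
  if (!is.numeric(temp) || any(!is.finite(temp)))
    stop("temp must be finite")
  if (any(temp < 10 | temp > 40))
    stop("temp out of the physiological range [10, 40] C")
  1 - .policy_interp(temp, table$anchors_c, table$metabolic_reduction)
}

#' Minimum acceptable oxygen delivery at a given temperature
#'
#' The DO2 floor (mL O2/min/m2) interpolated piecewise linearly between the
#' policy anchors (286 at 37 C down to 80 at 18 C). The returned value is a
#' floor: delivered DO2 below it triggers a `do2_deficit` alarm.
#'
#' @inheritParams metabolic_fraction
#' @return DO2 floor(s) in mL O2/min/m2.
#' @export
#' @examples
#' do2_target(c(37, 30, 28))
do2_target <- function(temp, table = default_policy_table()) {
  if (!is.numeric(temp) || any(!is.finite(temp)))
    stop("temp must be finite")
  rng <- range(table$anchors_c)
  if (any(temp < rng[1] | temp > rng[2]))
    warning("temp outside the policy anchor range; holding nearest anchor")
  .policy_interp(temp, table$anchors_c, table$do2_min)
}

#' Fractional pump-flow reduction at a given temperature
#'
#' Piecewise-linear between the anchors: no reduction at 37 C, 12.5% at 32 C
#' (midpoint of the customary 10-15% band), 30% at 28 C, 50% at 22 C, and
#' 75% (very low flow) at 18 C.
#'
#' @inheritParams metabolic_fraction
#' @return Flow-reduction fraction(s) in `[0, 1]`.
#' @export
flow_reduction <- function(temp, table = default_policy_table()) {
  if (!is.numeric(temp) || any(!is.finite(temp)))
    stop("temp must be finite")
  .policy_interp(temp, table$anchors_c, table$flow_reduction)
}

#' Blood-gas management strategy at a given temperature
#'
#' Alpha-stat (temperature-uncorrected) at and above the switch temperature,
#' pH-stat (temperature-corrected) below. The 28 C switch point is
#' configurable via the policy table since either strategy is defensible at
#' moderate hypothermia.
#'
#' @inheritParams metabolic_fraction
#' @return Character vector of `"alpha-stat"` / `"pH-stat"`.
#' @export
ph_strategy <- function(temp, table = default_policy_table()) {
  if (!is.numeric(temp) || any(!is.finite(temp)))
    stop("temp must be finite")
  alpha <- if (table$ph_switch_inclusive) temp >= table$ph_switch_temp
           else temp > table$ph_switch_temp
  ifelse(alpha, "alpha-stat", "pH-stat")
}

#' Sweep-gas (CO2 removal) strategy at a given temperature
#'
#' Returns the label of the nearest policy anchor; ties are broken toward
#' the colder anchor (more aggressive CO2 sweep, the safer reading during
#' cooling toward acidosis-prone depths).
#'
#' @inheritParams metabolic_fraction
#' @return Character vector of strategy labels.
#' @export
co2_strategy <- function(temp, table = default_policy_table()) {
  if (!is.numeric(temp) || any(!is.finite(temp)))
    stop("temp must be finite")
  vapply(temp, function(tt) {
    d <- abs(table$anchors_c - tt)
    # anchors are sorted warm -> cold, so the last minimiser is the coldest
    table$co2_strategy[max(which(d == min(d)))]
  }, character(1))
}

#' Blood-gas parameters for DO2/flow conversion
#'
#' Parameters needed to convert a DO2 floor to a pump flow: arterial oxygen
#' content is `CaO2 = 1.36 * Hb * SaO2 + 0.003 * PaO2` (mL O2/dL). Defaults
#' reflect typical on-bypass hemodilution (Hb 10 g/dL) with full oxygenator
#' saturation.
#'
#' @param hemoglobin hemoglobin concentration, g/dL (> 0).
#' @param sao2 arterial oxygen saturation, fraction in `[0, 1]`.
#' @param pao2 arterial oxygen partial pressure, mmHg (>= 0).
#' @return An object of class `blood_gas_params`.
#' @export
blood_gas_params <- function(hemoglobin = 10, sao2 = 1.0, pao2 = 100) {
  stopifnot(is.numeric(hemoglobin), hemoglobin > 0,
            is.numeric(sao2), sao2 >= 0, sao2 <= 1,
            is.numeric(pao2), pao2 >= 0)
  structure(list(hemoglobin = hemoglobin, sao2 = sao2, pao2 = pao2),
            class = "blood_gas_params")
}

#' Arterial oxygen content
#'
#' @param gas a [blood_gas_params()].
#' @return CaO2 in mL O2/dL.
#' @export
arterial_o2_content <- function(gas) {
  1.36 * gas$hemoglobin * gas$sao2 + 0.003 * gas$pao2
}

#' Cardiac index required to deliver a DO2 target
#'
#' `CI = DO2 / (CaO2 * 10)` with CaO2 in mL O2/dL, giving CI in L/min/m2.
#'
#' @param do2 oxygen delivery target, mL O2/min/m2 (>= 0).
#' @param gas a [blood_gas_params()].
#' @return Cardiac index in L/min/m2.
#' @export
#' @examples
#' required_cardiac_index(286, blood_gas_params(hemoglobin = 10))
required_cardiac_index <- function(do2, gas = blood_gas_params()) {
  if (!is.numeric(do2) || any(!is.finite(do2)) || any(do2 < 0))
    stop("do2 must be finite and non-negative")
  cao2 <- arterial_o2_content(gas)
  if (cao2 <= 0) stop("arterial O2 content must be positive")
  do2 / (cao2 * 10)
}
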
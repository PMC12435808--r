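#' Measurement sites
#'
#' The five temperature-measurement sites monitored during bypass.
#' Arterial and venous probes observe the blood compartments, esophageal
#' and nasopharyngeal probes observe the core, and the bladder probe
#' observes a configured mixture of core and peripheral temperature.
#' @export
sensor_sites <- c("arterial", "venous", "esophageal",
                  "nasopharyngeal", "bladder")

.core_sites <- c("esophageal", "nasopharyngeal", "bladder")

#' Multi-site temperature sensor model
#'
#' Per-site Gaussian noise, constant bias, first-order lag, and a Poisson
#' dropout process. Scalars are recycled across the five sites of
#' [sensor_sites]. Defaults: 0.1 C noise, no bias, 5 s lag for the blood
#' probes, 30 s for esophageal/nasopharyngeal and 120 s for bladder
#' (plausible clinical probe dynamics), and 2 dropout events per hour per
#' site lasting 30-120 s — the reference dropout model for the Monte-Carlo
#' study.
#'
#' @param noise_sd per-site noise standard deviation, C (>= 0).
#' @param bias per-site constant bias, C.
#' @param lag_s per-site first-order lag time constant, s (0 = none).
#' @param dropout_rate_per_hour Poisson rate of dropout onsets per site.
#' @param dropout_duration_s length-2 range (s) from which each dropout
#'   duration is drawn uniformly.
#' @param bladder_core_weight weight of core temperature in the bladder
#'   probe's core/peripheral mixture.
#' @return An object of class `sensor_model`.
#' @export
sensor_model <- function(noise_sd = 0.1,
                         bias = 0,
                         lag_s = c(5, 5, 30, 30, 120),
                         dropout_rate_per_hour = 2,
                         dropout_duration_s = c(30, 120),
                         bladder_core_weight = 0.65) {
  rec <- function(x) {
    x <- rep_len(as.numeric(x), 5L)
    names(x) <- sensor_sites
    x
  }
  noise_sd <- rec(noise_sd); bias <- rec(bias); lag_s <- rec(lag_s)
  if (any(!is.finite(noise_sd)) || any(noise_sd < 0))
    stop("noise_sd must be finite and >= 0")
  if (any(!is.finite(lag_s)) || any(lag_s < 0))
    stop("lag_s must be finite and >= 0")
  if (!is.finite(dropout_rate_per_hour) || dropout_rate_per_hour < 0)
    stop("dropout_rate_per_hour must be >= 0")
  stopifnot(length(dropout_duration_s) == 2)
  if (any(dropout_duration_s <= 0) || diff(dropout_duration_s) < 0)
    stop("dropout_duration_s must be positive and ordered")
  if (bladder_core_weight < 0 || bladder_core_weight > 1)
    stop("bladder_core_weight must lie in [0, 1]")
  structure(list(noise_sd = noise_sd, bias = bias, lag_s = lag_s,
                 dropout_rate_per_hour = dropout_rate_per_hour,
                 dropout_duration_s = as.numeric(dropout_duration_s),
                 bladder_core_weight = bladder_core_weight),
            class = "sensor_model")
}

#' Ideal sensor model
#'
#' No noise, no bias, no lag, no dropout — the "perfect sensing"
#' configuration used for the deterministic reference runs.
#' @return A `sensor_model`.
#' @export
perfect_sensor_model <- function() {
  sensor_model(noise_sd = 0, bias = 0, lag_s = 0, dropout_rate_per_hour = 0)
}

# what each site would read with an ideal instantaneous probe
.site_truth <- function(ta, tv, tc, tp, w_bladder) {
  c(arterial = ta, venous = tv, esophageal = tc, nasopharyngeal = tc,
    bladder = w_bladder * tc + (1 - w_bladder) * tp)
}

#' Observe the thermal state through the sensor panel
#'
#' Each site reads its source compartment through a first-order lag, plus
#' constant bias, plus Gaussian noise (drawn from R's RNG, so results are
#' reproducible under [set.seed()]). Validity is supplied externally via
#' `valid`, normally a row of the mask produced by [dropout_process()];
#' invalid readings carry `NA` values.
#'
#' @param state a [thermal_state()].
#' @param model a [sensor_model()].
#' @param lag named numeric of the previous filtered site temperatures, or
#'   `NULL` to initialise the filters at the current truth.
#' @param valid logical vector of length 5 (validity per site).
#' @param dt time since the previous observation, s.
#' @return A `sensor_panel` data frame with columns `site`, `value`,
#'   `valid`, `time`, carrying the updated filter state in attribute
#'   `"lag"`.
#' @export
observe <- function(state, model, lag = NULL, valid = rep(TRUE, 5), dt = 1) {
  truth <- .site_truth(state$t_arterial, state$t_venous, state$t_core,
                       state$t_peripheral, model$bladder_core_weight)
  if (is.null(lag)) lag <- truth
  alpha <- ifelse(model$lag_s > 0, pmin(dt / model$lag_s, 1), 1)
  filt <- lag + alpha * (truth - lag)
  value <- filt + model$bias + stats::rnorm(5, 0, model$noise_sd)
  value[!valid] <- NA_real_
  panel <- data.frame(site = sensor_sites, value = as.numeric(value),
                      valid = as.logical(valid), time = state$time,
                      stringsAsFactors = FALSE)
  class(panel) <- c("sensor_panel", "data.frame")
  attr(panel, "lag") <- filt
  panel
}

#' Simulate the sensor dropout process
#'
#' Dropout onsets follow an independent Poisson process per site at the
#' configured rate; each event invalidates the site for a duration drawn
#' uniformly from the configured range. Deterministic under [set.seed()].
#'
#' @param model a [sensor_model()].
#' @param horizon length of the simulated interval, s (> 0).
#' @param dt tick length, s (> 0).
#' @return Logical matrix (`ceiling(horizon/dt)` ticks by 5 sites), `TRUE`
#'   where the site is valid, with the drawn events in attribute
#'   `"events"` (data frame `site`, `onset`, `duration`).
#' @export
dropout_process <- function(model, horizon, dt = 1) {
  if (!is.finite(horizon) || horizon <= 0) stop("horizon must be > 0")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  n <- ceiling(horizon / dt)
  mask <- matrix(TRUE, nrow = n, ncol = 5,
                 dimnames = list(NULL, sensor_sites))
  events <- list()
  rate <- model$dropout_rate_per_hour / 3600
  for (s in seq_along(sensor_sites)) {
    k <- stats::rpois(1, rate * horizon)
    if (k == 0) next
    onset <- sort(stats::runif(k, 0, horizon))
    dur <- stats::runif(k, model$dropout_duration_s[1],
                        model$dropout_duration_s[2])
    for (j in seq_len(k)) {
      i0 <- max(1L, floor(onset[j] / dt) + 1L)
      i1 <- min(n, ceiling((onset[j] + dur[j]) / dt))
      if (i0 <= i1) mask[i0:i1, s] <- FALSE
    }
    events[[s]] <- data.frame(site = sensor_sites[s], onset = onset,
                              duration = dur, stringsAsFactors = FALSE)
  }
  attr(mask, "events") <- if (length(events))
    do.call(rbind, events)
  else
    data.frame(site = character(), onset = numeric(), duration = numeric())
  mask
}

# internal scalar fusion used by the simulation loop; values/valid are the
# 5-vectors in sensor_sites order
.fuse_scalars <- function(value, valid, minimum_valid) {
  core_vals <- value[3:5][valid[3:5]]
  if (length(core_vals) >= minimum_valid) {
    core <- stats::median(core_vals)
    core_degraded <- FALSE
    core_avail <- TRUE
  } else if (valid[2]) {
    core <- value[2]
    core_degraded <- TRUE
    core_avail <- TRUE
  } else if (length(core_vals) >= 1) {
    core <- stats::median(core_vals)
    core_degraded <- TRUE
    core_avail <- TRUE
  } else {
    core <- NA_real_; core_degraded <- TRUE; core_avail <- FALSE
  }
  if (valid[1]) {
    blood <- value[1]; blood_degraded <- FALSE; blood_avail <- TRUE
  } else if (valid[2]) {
    blood <- value[2]; blood_degraded <- TRUE; blood_avail <- TRUE
  } else {
    blood <- NA_real_; blood_degraded <- TRUE; blood_avail <- FALSE
  }
  list(core = core, blood = blood,
       degraded = core_degraded || blood_degraded,
       available = core_avail && blood_avail)
}

#' Fuse the core-temperature estimate from redundant sites
#'
#' Median of the valid core-class readings (esophageal, nasopharyngeal,
#' bladder). If fewer than `minimum_valid` of them are valid, falls back to
#' the venous blood reading with a degraded-quality flag; failing that, to
#' any remaining valid core reading (degraded); with nothing valid the
#' estimate is signalled unavailable (`available = FALSE`), which the
#' controller consumes through its hold-last-safe-command contract.
#'
#' @param panel a `sensor_panel` from [observe()].
#' @param minimum_valid minimum number of valid core-class sites for a
#'   full-quality estimate (default 2).
#' @return List with `core` (C or `NA`), `degraded`, `available`.
#' @export
#' @examples
#' st <- thermal_state(t_core = 36.2)
#' p <- observe(st, perfect_sensor_model())
#' fuse_core(p)$core
fuse_core <- function(panel, minimum_valid = 2) {
  f <- .fuse_scalars(panel$value, panel$valid, minimum_valid)
  core_avail <- !is.na(f$core)
  list(core = f$core,
       degraded = if (core_avail) {
         sum(panel$valid[3:5]) < minimum_valid
       } else TRUE,
       available = core_avail)
}

#' Fused blood-temperature estimate
#'
#' Arterial reading when valid; venous as a degraded fallback; unavailable
#' otherwise.
#' @inheritParams fuse_core
#' @return List with `blood` (C or `NA`), `degraded`, `available`.
#' @export
fuse_blood <- function(panel) {
  f <- .fuse_scalars(panel$value, panel$valid, 2)
  list(blood = f$blood, degraded = !panel$valid[1],
       available = !is.na(f$blood))
}

#' Combined fused estimate for the controller
#'
#' Bundles [fuse_core()] and [fuse_blood()] into the structure the
#' controller consumes: `available` is `TRUE` only when both the core and
#' blood estimates exist.
#' @inheritParams fuse_core
#' @return List with `core`, `blood`, `degraded`, `available`.
#' @export
fuse_panel <- function(panel, minimum_valid = 2) {
  .fuse_scalars(panel$value, panel$valid, minimum_valid)
}
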
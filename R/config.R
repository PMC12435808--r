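#' Read a simulation configuration (and optional scenario) from YAML
#'
#' The document may contain the blocks `patient:`, `policy:`,
#' `controller:`, `sensors:`, `safety:`, `blood_gas:`, `scenario:` and the
#' scalar `dt:`. Each block's keys must be arguments of the corresponding
#' constructor ([patient_params()], [policy_table()],
#' [controller_config()], [sensor_model()], [safety_config()],
#' [blood_gas_params()], [scenario()]); unknown blocks or keys are
#' rejected, and every constructor's validity checks apply (for example a
#' policy override violating the monotonicity invariants fails at load
#' time).
#'
#' @param path YAML file path.
#' @return List with `config` (a [sim_config()]) and `scenario` (a
#'   [scenario()] or `NULL`).
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  builders <- list(patient = patient_params,
                   policy = policy_table,
                   controller = controller_config,
                   sensors = sensor_model,
                   safety = safety_config,
                   blood_gas = blood_gas_params,
                   scenario = scenario)
  known <- c(names(builders), "dt")
  unknown <- setdiff(names(doc), known)
  if (length(unknown))
    stop("unknown configuration block(s): ",
         paste(unknown, collapse = ", "))
  built <- list()
  for (blk in names(builders)) {
    args <- doc[[blk]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(builders[[blk]])))
    if (length(bad))
      stop("unknown key(s) in '", blk, "' block: ",
           paste(bad, collapse = ", "))
    # yaml returns vectors as lists sometimes; flatten length-N numerics
    args <- lapply(args, function(a)
      if (is.list(a) && all(vapply(a, is.numeric, logical(1))))
        unlist(a) else a)
    built[[blk]] <- do.call(builders[[blk]], args)
  }
  cfg <- sim_config(patient = built$patient, controller = built$controller,
                    sensors = built$sensors, safety = built$safety,
                    policy = built$policy, blood_gas = built$blood_gas,
                    dt = if (is.null(doc$dt)) 1 else doc$dt)
  scen <- if (is.null(doc$scenario)) NULL else built$scenario
  list(config = cfg, scenario = scen)
}
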
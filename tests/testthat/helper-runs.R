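# Shared fixtures: the deterministic deep-hypothermia reference run (perfect
# sensing) is used by many tests; compute it once per test session.

.run_cache <- new.env(parent = emptyenv())

reference_scenario <- function(seed = 1L) {
  scenario(name = "deep_hypothermia", initial_temp = 37,
           target_core_temp = 20, rewarm_permitted_min = 90,
           duration_min = 260, deep_hypothermia = TRUE, seed = seed)
}

perfect_config <- function() sim_config(sensors = perfect_sensor_model())

reference_run <- function() {
  if (is.null(.run_cache$ref))
    .run_cache$ref <- run_scenario(reference_scenario(), perfect_config())
  .run_cache$ref
}

# short cooling-only scenario (37 -> 28) for cheaper checks
cooling_run <- function() {
  if (is.null(.run_cache$cool)) {
    sc <- scenario(name = "moderate_cooling", target_core_temp = 28,
                   rewarm_permitted_min = 1e6, duration_min = 70,
                   deep_hypothermia = FALSE, seed = 7L)
    .run_cache$cool <- run_scenario(sc, perfect_config())
  }
  .run_cache$cool
}

make_panel <- function(values, valid = rep(TRUE, 5), time = 0) {
  data.frame(site = sensor_sites, value = values, valid = valid,
             time = time, stringsAsFactors = FALSE)
}
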
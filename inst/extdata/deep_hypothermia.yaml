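# Reference deep-hypothermia scenario: cool 37 -> 20 C, maintain, rewarm
# to 32 C once permitted (90 min), final-rewarm to 36-37 C, wean.
dt: 1
controller:
  target_core_temp: 20
  cooling_rate_min_per_degc: 4
  final_rewarming_rate_min_per_degc: 5
sensors:
  noise_sd: 0.1
  dropout_rate_per_hour: 2
  dropout_duration_s: [30, 120]
scenario:
  name: deep_hypothermia
  initial_temp: 37
  target_core_temp: 20
  rewarm_permitted_min: 90
  duration_min: 260
  deep_hypothermia: true
  seed: 20250915
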
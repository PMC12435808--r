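---
title: "Closed-loop temperature management on bypass: model, controller and validation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop temperature management on bypass}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perfusim)
```

## The problem

During cardiopulmonary bypass (CPB) the perfusionist controls the
patient's temperature through the heater–cooler unit (HCU): water at a
commanded temperature flows through the oxygenator heat exchanger and
heats or cools the blood, which in turn heats or cools the body. Manual
control of this loop is workload-intensive and variable; the clinically
accepted safety envelope, however, is crisp and quantitative:

* cooling gradient: blood may be at most **10 °C warmer than the HCU
  water**;
* rewarming gradient: blood may be at most **4 °C warmer than the core**
  (to limit outgassing and cerebral thermal stress);
* rate: commanded temperature change of at most **1 °C per 3–5 min**
  (1 °C per 5 min in the final rewarming stage);
* absolute bounds: water setpoints within **18–37 °C**;
* temperature-indexed perfusion policy: as the patient cools, metabolic
  demand falls, so the oxygen-delivery floor, pump flow, blood-gas (pH)
  strategy and sweep-gas (CO₂) strategy all track temperature.

`perfusim` implements an automated controller for this envelope and — in
the absence of a hardware test bench — a synthetic patient to close the
loop against, a multi-site sensor layer with realistic failures, a
debounced alarm engine, and a seeded Monte-Carlo harness that measures
how often the closed loop respects the gradient envelope when sensors
drop out.

## The patient model

The patient is a lumped-compartment network: arterial blood, venous
blood, core and peripheral compartments, plus the HCU water temperature
as a first-order actuator state. Energy balances are linear in the
temperature differences:

* heat enters arterial blood through the heat exchanger at
  $\varepsilon\, G_{hx}\, f \,(T_w - T_v)$, where $f$ is pump flow as a
  fraction of standard flow (convective transfer is flow-dominated, so
  the exchanger conductance scales linearly with $f$);
* arterial and venous blood exchange through a circulatory mixing
  conductance; venous blood exchanges with the core; the core with the
  peripheral shell;
* metabolic heat enters the core as
  $Q_{37}\,\phi(T_{core})$ where $\phi$ is the policy table's metabolic
  fraction (1.0 at 37 °C down to 0.15 at 18 °C) — a single consistent
  source for temperature-dependent metabolism.

Integration is explicit Euler at `dt = 1 s` (configurable). The fastest
node (arterial blood, ≈ 5 s time constant with default parameters) is
comfortably inside the Euler stability region, and the test suite checks
that halving `dt` moves no temperature by more than 0.05 °C at one hour.

Default parameters describe a 70 kg adult (BSA 1.8 m²): 5 L blood, 40 kg
core, 25 kg peripheral shell, and a 72 W normothermic metabolic rate
(≈ anesthetized basal). Conductances were chosen once so that both ends
of the protocol are physically reachable: an unconstrained HCU at the
full 10 °C gradient cools the body at about 1 °C per 2.5–3 min at
operating flows, and rewarming under the 4 °C blood–core ceiling
proceeds at a clinically typical 6–9 min per degree. Tuning the model
slower on the cooling side (≈ 1 °C per 3–4 min) would make rewarming
under the 4 °C ceiling take over 20 min per degree and the full protocol
would not complete in a realistic bypass; this compromise is documented
here as the package's own choice.

What the model does **not** emulate: spatially resolved bioheat
transfer, pharmacologic and anesthetic effects on metabolism and
vascular tone, cardioplegia circuits, and acid–base chemistry (the
pH/CO₂ strategies are policy labels, not simulated chemistry).
Consequently, a passing test suite shows the *controller* honours its
envelope against a plausible thermal plant — it is not evidence about
any particular patient's thermal response.

## The policy tables

Five anchors (37, 32, 28, 22, 18 °C) carry the temperature-indexed
policy: metabolic reduction (0/20/50/75/85 %), DO₂ floors
(286/220/180/120/80 mL O₂/min/m²), flow reduction (0/12.5/30/50/75 %),
pH strategy (alpha-stat at ≥ 28 °C, pH-stat below; the 28 °C row is
institutionally ambiguous and therefore configurable), and CO₂ sweep
labels (nearest anchor, ties to the colder — the more protective
reading while cooling). Between anchors the tables interpolate
piecewise-linearly: with only five published anchors, linearity is the
minimal assumption that preserves monotonicity. Values quoted as
approximate ("~20 %", "~10–15 %") are fixed once: band midpoints (12.5 %
at 32 °C), and the 18 °C flow row — which admits either circulatory
arrest or very low flow — defaults to 75 % reduction with an explicit
scenario-level `circulatory_arrest` interval for the arrest reading.

```{r policies}
do2_target(c(37, 30, 28, 20))
metabolic_fraction(c(37, 25, 18))
required_cardiac_index(286, blood_gas_params(hemoglobin = 10))
```

The DO₂→flow conversion uses standard perfusion physiology,
$CI = DO_2 / (10\,CaO_2)$ with
$CaO_2 = 1.36\,Hb\,SaO_2 + 0.003\,PaO_2$; defaults reflect on-bypass
hemodilution (Hb 10 g/dL, full oxygenator saturation). Baseline VO₂
defaults to 120 mL O₂/min/m² at 37 °C, which closes the monitoring
loop: the suite verifies the DO₂ floor covers temperature-scaled
consumption at every temperature in [18, 37] °C.

## The controller

A six-phase state machine — `STANDBY`, `COOLING`, `MAINTENANCE`,
`REWARMING`, `FINAL_REWARMING`, `WEANING` — mirrors the protocol
stages. Transitions are gated: cooling ends when the fused core enters a
±0.2 °C band around the target; rewarming requires explicit surgical
permission; final rewarming begins at 32 °C; weaning requires the core
to hold 36–37 °C with the DO₂ floor met for a sustained 5-minute window.
The band and window are deliberately conservative defaults for the
protocol's unquantified "stable" criteria, and both are configurable.
A normothermic target never leaves `STANDBY`: the same servo machinery
holds the target, so tepid management shares one code path with
hypothermic management.

Each tick the controller:

1. advances a **rate-limited trajectory target** toward the phase goal
   (1 °C/4 min by default — the midpoint of the accepted 3–5 min band,
   with values outside that band rejected at configuration time; 1 °C/5
   min in final rewarming);
2. **servoes** the HCU setpoint around the trajectory with
   proportional–integral action on the fused core error (gains 3 and
   1/240 s⁻¹; the integral's authority is capped at ±5 °C with
   conditional integration as anti-windup). Pure setpoint = trajectory
   would stall above the target by the metabolic offset; the servo is
   what closes that gap;
3. **clamps**: during cooling the setpoint may not fall more than 10 °C
   below the fused blood temperature; during rewarming it may not rise
   more than 4 °C above the fused core. The rewarming clamp is placed on
   the *water* temperature because in this plant the arterial blood
   temperature is always a convex combination of the water and tissue
   temperatures — bounding the water by core + 4 °C therefore bounds
   every reachable blood temperature, making the blood–core constraint
   hold by construction rather than by feedback. A brute-force search
   over candidate setpoints (forward-simulating the plant) confirms in
   the test suite that this clamp is never less safe than the largest
   empirically safe setpoint. Finally the setpoint is clamped to
   [18, 37] °C.

On total sensing loss the controller re-emits its previous command with
a `hold` flag (hold-last-safe-command), and the safety layer raises a
sensor-loss alarm.

## Sensing and fusion

Five sites (arterial, venous, esophageal, nasopharyngeal, bladder) read
their source compartments through first-order lags (5/5/30/30/120 s),
constant bias (0 by default), and Gaussian noise (0.1 °C). The bladder
probe reads a 65/35 core/peripheral mixture. Dropout is a per-site
Poisson process; the reference model is 2 events/hour/site lasting
30–120 s. These rates define the package's reference dropout
experiment; they are stated here because no standard benchmark exists
for probe dropout, and they are deliberately pessimistic relative to
routine clinical experience.

The core estimate is the **median** of the valid core-class sites —
robust to any single failed-high or failed-low probe, unlike a mean.
With fewer than two valid core sites the estimate falls back to the
venous blood reading (flagged degraded), then to any remaining valid
core reading, and only then is declared unavailable, which triggers the
controller's hold contract.

## Alarms

Seven alarm kinds (gradient breach, commanded-rate breach, absolute
bound, measured rewarming rate, sensor loss, DO₂ deficit, low rSO₂)
plus an `override` audit record. Conditions are evaluated against the
*true* state for the thermal constraints — the engine's contract is
completeness with respect to ground truth, verified by fault-injection
tests. Every kind is debounced (3 ticks) and re-arms only after a
sustained clear (10 ticks): debounce/hysteresis is the concrete
mitigation for alarm fatigue. Two nuisance thresholds are worth noting:
the absolute-bound alarm carries a 0.2 °C margin because a patient
starting at 37 °C unavoidably drifts about a tenth of a degree upward
before the water pulls away, and the measured-rate alarm only compares
estimates taken with all three core sites valid, because losing even one
site changes the fusion (a two-site mean that includes the slow bladder
probe) enough to mimic most of a degree of change with no real
temperature movement. The rSO₂
channel is synthetic (baseline 65 %, alarm at a 20 % relative drop,
driven by the DO₂ sufficiency ratio); it is a labelled extension point,
not NIRS physics.

## The reference experiment

The deep-hypothermia scenario drives the full protocol: cool 37 → 20 °C
(target inside the customary 18–22 °C band), maintain, rewarm to 32 °C
once permitted at 90 min, final-rewarm to 36–37 °C, wean; 260 simulated
minutes at `dt = 1 s` (15 600 ticks). Under perfect sensing this run is
deterministic and must achieve compliance 1.0 with zero safety alarms —
the controller is safe by construction when it can see.

**Gradient compliance** is the fraction of *constrained* ticks
satisfying the phase-conditional envelope: blood − water ≤ 10 °C over
cooling ticks, blood − core ≤ 4 °C over rewarming ticks, evaluated on
the true state. Constraints are phase-conditional because each gradient
is defined for the phase it protects; unconstrained ticks (maintenance,
weaning, standby) are excluded from the denominator so they cannot
dilute breaches.

The Monte-Carlo study repeats the scenario under the reference dropout
model with 50 consecutive seeds and reports the distribution of
compliance. Fifty runs of 15 600 ticks keep the study within a few
minutes on one CPU while the binomial uncertainty on a ≥ 97 % compliance
claim is already far below the margin observed (mean compliance in this
configuration is ≈ 99.9 %).

```{r study, eval = FALSE}
study <- dropout_study(50, scenario(), sim_config(),
                       base_seed = 20250915)
study$mean_compliance
```

Every run is bit-reproducible from its seed, carries an md5 hash of its
full configuration, streams to a CSV whose audit mode recomputes the
compliance metric identically, and logs alarms as JSON lines.

## Known limitations

* The plant is a four-node caricature; compliance results transfer to
  reality only to the extent that real blood–tissue heat transfer is no
  *faster* than modelled (the clamps are conservative under slower
  plants).
* Sensor faults are limited to noise, constant bias and dropout; drift
  and correlated failures (e.g. a disconnected cable affecting several
  channels) are out of scope.
* The servo's integral authority (±5 °C) deliberately cannot compensate
  a large constant bias on all core probes; such a fault surfaces as a
  stalled phase rather than a masked unsafe command, which is the
  intended failure direction.
* The 18 °C circulatory-arrest row, pH strategy at 28 °C, and the
  stability band/window are configuration, not claims: the protocol
  sources leave them to institutional judgment.
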
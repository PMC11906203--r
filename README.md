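# breathsim

A lumped-parameter in-silico twin of a mechanical infant breathing model.
A single compliant lung (0.7 mL/mbar) is driven through a prescribed tidal
waveform (44 breaths/min, 35 mL between 30 and 65 mL) and breathes through a
configurable airway — a laminar tube, sharp-edged orifices with a quadratic
pressure law, or both — optionally into a bedding **gas-storage compartment**
that recycles part of each exhalation back into the next inhalation.

The point of the design is that the two candidate mechanisms of
bedding-related suffocation can be dialed in independently:

* **Airflow resistance** raises the work of breathing (WOB), measured as the
  area of the pressure–volume loop's inspiratory limb against sub-ambient
  pressure, without changing equilibrium lung CO₂.
* **CO₂ rebreathing** (gas storage) raises equilibrium lung CO₂ without
  materially changing WOB.

An analytic per-breath linear recurrence (`breath_steady_state()`) gives the
engine's equilibrium in closed form and serves as an independent oracle, as do
closed-form WOB expressions for sinusoidal drivers through linear and
quadratic resistances.

## Quick start

```r
library(breathsim)

# open tube only: resistance without storage
sim <- run_simulation(sim_config())
glance(sim)
#> co2_pct 4.44, etco2_mmHg 41.7, wob_J_min 0.0345, converged TRUE (breath 13)

# add a 1.93 mm orifice and a "wrapped" (8-layer) polyfill compartment
cfg <- sim_config(
  airway  = airway(tube_element(), orifice_element(1.93)),
  storage = polyfill_storage(8)
)
sim2 <- run_simulation(cfg)
glance(sim2)
#> co2_pct 8.28, wob_J_min 1.35, converged TRUE

autoplot(sim, type = "pv")        # pressure-volume loop
tidy(sim, what = "breaths")       # per-breath gas table

# analytic oracle for the same storage condition
breath_steady_state(storage_volume = 40)
#> lung_fCO2 0.0828, bounded TRUE
```

The bench protocol's three series are one call each:

```r
s1 <- run_series(1)   # open tube + 5 orifices: WOB rises ~400x, CO2 flat
s2 <- run_series(2)   # polyfill ladder 0-8 layers: CO2 4.44 -> 8.28 vol%
s3 <- run_series(3)   # 3x3 combination grid: effects are additive
attr(s2, "assertions")
autoplot(s3)
```

A command-line front end lives in `exec/breathsim`:

```sh
Rscript exec/breathsim simulate --config cfg.yaml --out trace.csv
Rscript exec/breathsim wob --in trace.csv
Rscript exec/breathsim series2 --out report.csv   # + report.csv.log
Rscript exec/breathsim fixture --kind ellipse --out pv.csv
```

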
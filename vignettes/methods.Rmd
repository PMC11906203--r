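---
title: "Model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathsim)
```

`breathsim` is a lumped-parameter in-silico twin of a mechanical infant
breathing model. It separates the two candidate mechanisms of bedding-related
suffocation — added **airflow resistance** (work of breathing) and **CO~2~
rebreathing** (gas storage in the bedding) — so each can be dialed in
independently and measured at equilibrium.

## The mechanical model

A single well-mixed compliant lung (compliance 0.7 mL/mbar) is driven through a
prescribed tidal volume waveform: 44 breaths/min, 35 mL tidal volume between 30
and 65 mL, sinusoidal by default (a trapezoid driver with configurable rise
fraction is also available). Because the volume trajectory is prescribed, the
airway pressure is purely resistive:

$$p_\mathrm{aw}(t) = -\,\Delta P\big(Q(t)\big), \qquad Q = \frac{dV}{dt},$$

summed over the series airway elements:

* **Tube** (laminar, Poiseuille): $R = 8\mu L/(\pi r^4)$. The default 300 mm ×
  5 mm tube with air viscosity $1.81\times10^{-5}$ Pa·s gives
  $R = 3.54\times10^{-3}$ mbar·s/mL.
* **Orifice** (sharp-edged, quadratic): $\Delta P = \rho\,Q|Q| / (2 C_d^2 A^2)$
  with $C_d = 0.6$, $\rho = 1.2$ kg/m³. The stock diameters are 4.03, 3.25,
  2.64, 1.93 and 1.07 mm.
* **Resistor**: an arbitrary linear resistance, for synthetic cases.

```{r}
airway(tube_element(), orifice_element(2.64))
```

## Gas transport

Three species are tracked (CO~2~, O~2~, balance). A volume-neutral metabolic
source injects CO~2~ at $0.044 \times V_T \times f$ = 67.76 mL/min and removes
O~2~ at that rate divided by the respiratory quotient 0.8, compensating the
volume imbalance in the balance gas so that airway flow equals $dV/dt$ exactly.
(A `volume_mode = "net"` option instead pushes the imbalance through the
airway.) The volume-neutral choice makes the engine's equilibrium coincide with
the analytic per-breath recurrence below, which is what lets the recurrence act
as an exact oracle.

The optional **storage compartment** models bedding (polyfill) as a single
well-mixed gas volume $V_s$ with three parameters:

* **entrainment** $\beta$ — the fraction of each inhaled tidal volume drawn
  from storage rather than ambient (effective
  $\beta_\mathrm{eff} = \min(\beta, V_s/V_T)$);
* **retention** $a$ — the fraction of the storage gas's deviation from ambient
  that survives the inter-breath washout,
  $g \leftarrow \mathrm{amb} + a\,(g - \mathrm{amb})$;
* **resistance** — an added linear airway resistance.

Exhaled gas accumulates into the compartment with volume-weighted mixing;
overflow beyond $V_s$ is vented at the mixed composition at the breath
boundary. The polyfill calibration maps one layer to 5 mL of storage
(`kappa_ml_per_layer = 5`), retention 0.5, and $2\times10^{-4}$ mbar·s/mL of
resistance per layer; "wrapped" is 8 layers (40 mL $\ge V_T$, so
$\beta_\mathrm{eff} = 1$). These three constants are a calibration choice: they
place the layer ladder's equilibrium CO~2~ in the observed 4–9 vol% band while
keeping the storage medium's resistive contribution small.

## Work of breathing

The analyzer segments a pressure–volume record into breaths at interior volume
minima and integrates the inspiratory limb against sub-ambient pressure with
the trapezoid rule:

$$W = \int_{\mathrm{insp},\ p<0} (-p)\, dV, \qquad
  1\ \mathrm{mbar\,mL} = 10^{-4}\ \mathrm{J}.$$

Two closed forms serve as independent oracles: for a linear resistance and
sinusoidal driver, $W = \pi R \omega V_T^2/8$; for a quadratic orifice,
$W = \tfrac{4}{3} K Q_0^3 / \omega$ with peak flow $Q_0 = \omega V_T/2$. A
half-ellipse loop of semi-axes $(a, b)$ has $W = \pi a b / 2$.

```{r}
fx <- generate_pv_fixture("linear_sinusoid", r_lin = 0.01)
c(measured = wob_summary(fx$data)$mean_work_J, expected = fx$expected_wob_J)
```

## The analytic per-breath recurrence

Discretizing one breath (inhale a tidal volume of the entrainment-weighted
storage/ambient blend plus the metabolic source; exhale a tidal volume at the
mixed lung fraction into storage; wash out) yields, per species, a linear map
on the pair (lung fraction, storage fraction). Its fixed point is a direct
2×2 solve; it exists iff the spectral radius is below 1. At $\beta = 1$,
$a = 1$, $V_s \ge V_T$ the radius reaches 1 — zero net CO~2~ export — and lung
CO~2~ grows without bound. In the fresh-air limit the exhaled CO~2~ fraction is
exactly ambient + injection-per-breath / $V_T$ = 0.0004 + 1.54/35 = 0.0444.

```{r}
breath_steady_state(storage_volume = 20)
```

## Numerical choices

* **Timestep**: 200 steps per breath by default (period/200); finer steps are
  accepted, coarser rejected. The engine-versus-recurrence discrepancy at this
  resolution is below 0.01 vol%.
* **Equilibrium**: converged when the exhaled CO~2~ fraction changes by less
  than `eq_tol = 1e-4` across each of 5 consecutive breaths.
* **Unbounded runs**: with $\beta = 1$, $a = 1$ the lung composition saturates
  toward 100% CO~2~ after roughly 45 breaths, after which the exhaled fraction
  can no longer change and the windowed detector would report a spurious
  plateau. Study the pre-saturation regime (`max_breaths` ≲ 40), where the
  monotone unbounded growth and the `converged = FALSE` flag are meaningful;
  the recurrence's `bounded = FALSE` flag is exact at any horizon.

## Units and conventions

Pressures are mbar, volumes mL, flows mL/s, work J. Gas fractions convert to
partial pressures under a **dry** convention by default (760 mmHg total):
0.21 → 159.6 ≈ 160 mmHg, 0.0004 → 0.304 ≈ 0.3 mmHg; a BTPS convention
(subtracting 47 mmHg water vapor) is available via
`convention_btps()`.

```{r}
fraction_to_partial_pressure(0.21)
fraction_to_partial_pressure(0.0004)
```

## The three test series

`run_series()` reproduces the bench protocol: series 1 (open tube + 5
orifices, no storage) shows WOB rising ~400× while equilibrium CO~2~ does not
move; series 2 (layer ladder 0–8) shows CO~2~ climbing from 4.4 to 8.3 vol%
while WOB stays within 0.2% of the series-1 range; series 3 (3×3 grid) shows
the two effects composing additively. Each result carries a machine-checked
assertion table in `attr(, "assertions")`.

```{r, eval = FALSE}
s2 <- run_series(2)
attr(s2, "assertions")
autoplot(s2)
```

## Limitations

* Pressure is purely resistive (flow through the airway); elastic and inertial
  pressure components inside the bellows are not modeled, so absolute WOB
  values are comparable across conditions but not to bench transducer
  readings.
* No anatomical dead space, no physiological compensation (the drive waveform
  never responds to blood gases), single well-mixed compartments throughout.
* The storage compartment exchanges gas at breath boundaries, not
  continuously; this is exact for the per-breath mass balance but does not
  resolve intra-breath concentration dynamics.
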
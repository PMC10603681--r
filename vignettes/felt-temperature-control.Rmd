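---
title: "Felt-temperature comfort modelling and the ventilation state machine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Felt-temperature comfort modelling and the ventilation state machine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broilervent)
```

## The comfort model

Broiler performance depends on keeping the birds inside a thermal comfort
zone that narrows and cools as they age. The controlling quantity is the
felt temperature

$$t_f = t_i - t_{cw} + t_{cRH},$$

the air temperature at bird level corrected down for the cooling effect of
moving air and up for the loss of evaporative cooling under excess
humidity. Both corrections are tabulated, not computed from psychrometric
theory: the package deliberately stays with the published lookup grids and
does not add dew-point or enthalpy calculations.

**Wind chill** (`wind_chill()`). The packaged grid covers 18–38 °C in
1-degree rows and 0.5–2.5 m/s in quarter-steps for 7-week-old birds.
Air speeds at or below 0.5 m/s produce no chill, and the 38 °C row is
zero — at body-temperature air, airflow no longer removes heat. Inside the
grid the lookup is bilinear; inputs beyond the hull are clamped to it.
Some low-temperature/high-speed cells are marked undefined in the source
table: these are speed/temperature combinations the controller must never
command (they would chill the birds dangerously). A query landing there is
evaluated at the nearest defined speed column and flagged through the
`x_clamped` attribute rather than raised as an error, because during
sensor replay such a query can legitimately arise from measurement noise.

Grids for younger birds are not published, only described as derived by
interpolation. We therefore scale the 7-week grid by an age factor,
piecewise linear from 0.3 at day 1 to 1.0 at day 35. This curve is an
explicit stand-in — young chicks are far more sensitive to draught, and
the factor encodes only that qualitative shape. Users with breed-specific
tables should supply them via `comfort_tables(age_scale = ...)` or replace
the grid wholesale.

**Humidity correction** (`rh_correction()`). The correction applies when
indoor RH exceeds the upper limit of the age band's humidity range by more
than one percentage point. The excess is binned (1–5, 5–10, …, 20–25,
>25 points); within a bin the grid is interpolated linearly between its
1-degree temperature rows and held piecewise-constant across bins, exactly
as the source binning prints it. One ambiguity deserves a note: the grid's
header defines the excess relative to an "optimal" RH while the
surrounding text triggers the correction above the band **maximum**. We
measure from the band maximum (`rh_max` of the age band), which is the
interpretation consistent with the correction being zero anywhere inside
the allowed band; the alternative reading would penalise humidities the
schedule itself declares acceptable.

**Setpoints** (`setpoints()`). The age schedule stores `tmax`/`tmin` per
band; the optimum is never tabulated and is taken as the band midpoint,
which reproduces the reference system's derived 25.5 °C for a 14-day
flock (band 24–27 °C). The open-ended "over 35 days" band prints a single
temperature; we set `tmin = tmax = topt = 18` there by default, making the
adult comfort band degenerate — deliberate, and overridable by editing the
schedule, since the source gives no width for it.

**The inverse problem** (`optimal_airspeed()`). Tunnel ventilation needs
the smallest air speed whose felt temperature reaches the optimum. We scan
a fixed 0.05 m/s grid from 0.5 m/s to the age's maximum permissible speed
(`max_airspeed()`: 0.8 m/s up to day 7, linear to 2.5 m/s at day 49).
0.05 m/s is finer than any real fan/VFD installation resolves and keeps
the search exhaustively testable; because the felt temperature is monotone
in air speed, the first grid point at or below the optimum is the answer.
When even the maximum speed cannot reach the optimum the result saturates
at the maximum and is flagged; the controller then simply runs flat out,
which is not an emergency — there is nothing more it could do.

## The controller

`controller_step()` advances a discrete clock (default tick 1 s; all
timers are integer ticks). At each cycle boundary the indoor temperature
is re-measured and the branch re-selected by where it falls against the
age band: below `tmin` → M1, up to the optimum → M2, up to `tmax` → TR,
above → TU. The source flowcharts never state the M1/M2 boundary
explicitly; placing it at `tmin` reproduces the reference trace's heater
behaviour (100 % at 22 °C, 10 % modulation at 25 °C against the 24–27 °C
band), so that is the boundary we use.

Branch behaviour in brief:

* **M1/M2**: gases checked first. Tunnel and pads off, heater set (M1:
  100 %; M2: `heater_gain` — default 20 %/°C, i.e. 10 % at half a degree
  below optimum — clamped to 0–100), blinds to the position looked up from
  the indoor-outdoor difference and flock live weight, ventilation at the
  power mapped to that position. After the settling time `ts4` (10 s) the
  differential pressure is regulated by proportional steps toward the
  17.5–30 Pa band midpoint, at most `dp$max_iter` corrections per cycle
  before a one-time fault alert. Ventilation stops when the cumulative
  on-time reaches `ts3` (30 s); if the under-roof air is then more than
  `dt3_max` (3 °C, invented, configurable) warmer than bird level, the
  circulation fans run for the rest of the cycle. At the cycle end RH is
  checked: out-of-band readings send a one-time message and move the next
  cycle's `ts3` by ±5 s within [10 s, 60 s] (drier air → shorter pulses).
  Step and bounds are invented and configurable; the derived timers
  `ts5 = ts3 − ts4` and `ts6 = ts2·60 − ts3` are never stored separately,
  so their invariants hold by construction.
* **TR**: as M1/M2 but continuous ventilation, heater and circulation off,
  and humidity excursions are reported without retuning `ts3` —
  temperature holds priority. The reference trace shows the transitional
  blind one step wider than the minimum-ventilation lookup at the same
  temperature difference, which matches its purpose of moving more air;
  this is the configurable `tr_offset` (default +1).
* **TU**: gases checked (a violation here raises a one-time alert but not
  the emergency cycle — with tunnel airflow already far exceeding any
  blind-fed airing, there is no stronger action available, and the
  emergency machinery is reserved for the blind-fed branches). The felt
  temperature at the age's maximum speed decides: below `tmin` run at the
  optimal speed, inside the band run at maximum, above it start
  evaporative cooling unless outdoor RH is at or above 80 % (wet outdoor
  air cannot evaporate into the pads) or the pads are still in their
  drying lockout. Measured air speed is corrected when it deviates more
  than 10 % from the setpoint. After an evaporative cycle the controller
  does **not** return to temperature classification: it recomputes the
  felt temperature and either enters the closed monitoring cycle
  (`TU_EVAP_HOLD`, watching only felt temperature, air speed, gases and
  outdoor RH) or, when the felt temperature has dropped below `tmin` or
  outdoor RH has risen to the cutoff, the shutdown procedure
  (`EVAP_SHUTDOWN`): pads off, airflow at the optimal speed, held for the
  pad-drying time `ts_drying` (default 30 min — the source names the timer
  but gives no value; 30 min is a typical pad dry-out and is
  configurable). The pads cannot re-enable before that time has elapsed;
  this is the anti-mold rule, and the closed cycle has no other exit.
* **PREP**: one full-power airing cycle to flush disinfection fumes, then
  a thermostat holding the empty house inside `[tpmin, tpmax]` (default
  28–32 °C, bracketing the 30 °C litter target) with heater-only and
  ventilation-only cycles. The source describes this mode only loosely;
  the purge-then-thermostat reading is our interpretation.

**Cycle time.** The schedule is 7 min up to 14 days (brooding economy) and
5 min after, overridable by an explicit `timers$ts2`. The packaged
reference fixture pins `ts2 = 5` min because the published half-hour test
of a 14-day flock plainly runs 5-minute cycles; the schedule boundary and
the test flock's age collide exactly at day 14, and we keep both the
schedule default and the explicit fixture override rather than silently
shifting the boundary.

**Emergencies.** Any gas at its limit (H₂S: any detectable amount above a
0.1 ppm noise floor — "absent" is not testable below sensor resolution)
shortens the cycle to 3 min, keeps ventilation running the whole cycle and
opens the blinds wide: in M1 only two steps wider than the lookup, to
spare the young birds; in M2/TR to the maximum by default. The published
trace reports position 4 rather than the maximum 7 in its M2 emergency, so
the emergency opening is configurable (`max`, `x_plus_2`, `fixed`) and the
packaged fixture uses `fixed` at 4 to match; the flowchart/trace
discrepancy is inherited from the source, not resolvable here.

**Messages.** Alerts are one-time per condition episode: a latch set on
first emission and cleared after one full cycle in which the condition was
absent. The emergency alert payload reports both the measured value and
the limit, because the published example message prints the limit while
the injected reading was higher — reporting both serves either reading.

**Blind map and fan powers.** The position lookup (temperature difference
× live weight) and the per-position fan powers are installation-specific
by nature; the source itself uses sample values. The defaults and the
packaged fixture map are chosen to reproduce the published example
positions and are expected to be replaced per building.

## The plant simulator

`plant_step()` is a lumped single-zone balance integrated by explicit
Euler at the controller tick: flock heat (11.6 kJ/h/kg — 129 kW for
20,000 birds at 2 kg, matching the published ~130 kW figure) plus heater
power against envelope conduction and ventilation air exchange; moisture
from the flock (4000 L/day for the reference 40-tonne flock, scaled by
live weight) and CO₂ (0.0008 m³/h/kg, invented) against ventilation
dilution; a stratification offset that relaxes toward 3.5 °C with still
air and collapses when circulation fans run; differential pressure from a
quadratic orifice law whose coefficient puts the default blind position 3
near the middle of the 17.5–30 Pa band; and tunnel air speed as flow over
the house cross-section. Pads pull the supply air toward a crude wet-bulb
estimate by an effectiveness factor.

Everything beyond the three cited source figures is an invented stand-in,
chosen once for physical plausibility: the model has no spatial gradients
beyond the single stratification offset, no litter chemistry, no bird
behaviour, no solar gain, and its humidity path uses a Magnus saturation
curve only to convert a well-mixed moisture balance into RH. Closed-loop
tests against it therefore demonstrate that the controller logic is
self-consistent and stabilising under first-order building dynamics — not
that any particular real house will hold the same trajectories. The
replay harness, which feeds recorded or published sensor traces directly,
is the stronger evidence for the decision logic itself.

Weather scenarios (`make_scenario()`) are deterministic given a seed:
seeded AR(1) noise around a sinusoidal day for cold/hot days, a Gaussian
CO₂ excursion for the gas-spike case, and the packaged reference trace
(sample-and-hold between its printed rows; the unprinted columns are
filled with in-band constants) for `"table5"`.

## Numerical choices and test scale

* Controller tick 1 s; timers in integer ticks; sensor values
  sample-and-held between trace rows.
* Explicit Euler for the plant; with default parameters the thermal time
  constant (≈ 2 h) is several orders above the tick, far inside the
  stability region. Parameter validation rejects non-positive physical
  constants at construction.
* Air-speed search grid 0.05 m/s; pressure and air-speed regulation are
  proportional with per-cycle iteration caps and one-time fault alerts
  rather than unbounded loops.
* Interpolation clamps at every grid hull; bin edges are half-open
  exactly as printed (an excess of exactly 5 points is the 1–5 bin).
* The test suite exercises closed-loop runs of two to three simulated
  hours at 1 s ticks and property sweeps of 100–1000 random points per
  invariant, sizes at which the whole suite runs in about a minute on one
  core while still crossing every branch of the state machine several
  times.

## Known limitations

* The age scaling of the wind-chill grid and the adult band width are
  stand-ins for unpublished tables; treat absolute felt temperatures for
  young flocks as indicative until real grids are supplied.
* The M1/M2 boundary, transitional blind offset, `dt3_max`, the `ts3`
  adjustment step and the pad-drying time are design choices documented
  above, not published constants.
* The simulator is a controller-testing plant, not a building-design
  model.
* Lighting, feeding, dust and microbial monitoring are out of scope, as is
  any transport binding (the trace file is the transport-neutral
  equivalent of a broker feed).
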
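# broilervent

Autonomous microclimate control for broiler houses: a felt-temperature
comfort model and a finite-state ventilation controller, with a building
simulator and a sensor-trace replay harness for testing the controller
without hardware.

## The problem

Broilers have a narrow thermal comfort zone that moves with age, and what
matters to the bird is not the dry-bulb air temperature but the *felt
temperature*

```
tf = ti − tcw + tcRH
```

where `ti` is the air temperature at bird level, `tcw` is a wind-chill
correction (moving air cools the birds; speeds at or below 0.5 m/s have no
effect) and `tcRH` is a humidity correction (excess relative humidity
blunts the birds' evaporative cooling, so the air feels warmer). Both
corrections come from lookup grids indexed by temperature, air speed and
the excess of RH over the age band's upper limit; the package ships the
grids as CSV data and interpolates between their rows and columns.

Around this model sits the controller a climate computer would run:

* **Building preparation (PREP)** — purge, then thermostat the empty house
  so the litter warms before chicks are housed.
* **Minimum ventilation (M1/M2)** — cold weather. Short fan pulses (30 s
  in a 5–7 min cycle) through inlet blinds, heating at full power (M1,
  below the comfort band) or modulated against the deficit below the
  optimum (M2), differential-pressure regulation to a 17.5–30 Pa band,
  circulation fans when the air stratifies, and a humidity check that
  retunes the pulse length each cycle.
* **Transitional ventilation (TR)** — continuous ventilation through
  wider-open blinds to remove the flock's heat, no heating.
* **Tunnel ventilation (TU)** — end-to-end airflow cooling the birds by
  wind chill, sized from the felt-temperature model (the inverse problem:
  the smallest air speed whose felt temperature reaches the optimum), with
  evaporative-pad cooling when even the maximum permissible air speed is
  not enough — vetoed when outdoor RH is 80 % or higher, held in a closed
  monitoring cycle while the pads are wet, and always followed by a pad
  drying period to prevent mold.

Harmful gases (NH₃ < 15 ppm, CO₂ < 3000 ppm, CO < 4.4 ppm, no H₂S) are
checked every cycle: at 80 % of a limit the blinds open one step wider; at
the limit the controller enters a 3-minute emergency cycle with maximum
airing and a one-time alert.

## Worked example

```r
library(broilervent)
ct <- comfort_tables()

setpoints(14, ct)
#> <setpoints> tmin 24.0, topt 25.50, tmax 27.0 degC; RH 70-75%

# a 7-week flock at 30 degC under a 2.5 m/s tunnel wind:
wind_chill(30, 2.5, 49, ct)        # 5.8  degC of chill
felt_temperature(30, 2.5, 60, 49, ct)  # 24.2 degC felt vs 30 measured

# replay the packaged reference trace through the controller
cfg <- read_config(reference_fixture("config"))
r   <- replay_trace(read_trace(reference_fixture("trace")), cfg, ct)
subset(r$events, kind != "actuator")
#>       t  kind       name                     value
#>       0 alert   m1_entry                        22
#>       0  mode       mode                        M1
#>     600  mode       mode                        TR
#>     900  mode       mode                        M2
#>    1500 alert gas_exceed CO2 3500 ppm (limit 3000)
#>    1500  mode  emergency                         1
#>    1680  mode  emergency                         0

compare_events(r$events, read_expectations(reference_fixture("expectations")))
#> Event comparison: 25/25 expectations met
```

The replayed half hour starts in minimum ventilation with the heater at
100 %, switches to transitional at minute 10 when the house warms past the
optimum, back to minimum at minute 15, widens the blind one step at minute
20 on a CO₂ pre-warning, enters a 3-minute emergency at minute 25 when CO₂
passes its limit (heater to 50 %, one-time alert reporting measurement and
limit), and returns to normal at minute 28.

A command-line front end for the same operations (`felt-temp`, `replay`,
`simulate`, `tables-dump`, `validate-config`) is installed at
`inst/cli/broilervent`.

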
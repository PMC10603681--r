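Package: broilervent
Title: Autonomous Microclimate Control for Broiler Houses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Felt-temperature (wind-chill and humidity corrected) comfort
    modelling for broiler chickens and a finite-state ventilation controller
    for poultry houses, covering building preparation, duty-cycled minimum
    ventilation, transitional ventilation and tunnel ventilation with
    evaporative cooling, gas-safety warnings and emergency handling, and
    differential-pressure regulation. Includes a lumped-parameter building
    and flock simulator for closed-loop testing, deterministic scenario
    generators, CSV sensor-trace replay, JSON-lines event logging, and an
    expectations comparator for validating controller behaviour against
    reference traces.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
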
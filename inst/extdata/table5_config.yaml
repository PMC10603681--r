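# Controller configuration for the packaged reference replay trace
# (single blind with seven positions; 14-day-old flock at full stocking).
tick: 1
n_positions: 7
flock:
  N: 20000
  age: 14
blinds:
  dt1_breaks: [0, 5, 15]
  weight_breaks: []
  positions: [5, 4, 3, 2]
  tr_offset: 1
fans:
  power_map: [15, 25, 35, 45, 55, 65, 75]
  tunnel_full_saf: 3.0
timers:
  ts2: 5          # min; explicit override of the age schedule
  ts3: 30         # s
  ts4: 10         # s
  ts3_step: 5
  ts3_bounds: [10, 60]
  ts_drying: 30   # min
  emergency_ts2: 3
dp:
  band: [17.5, 30]
  gain: 1.0
  max_iter: 20
gas:
  NH3_max: 15
  CO2_max: 3000
  CO_max: 4.4
  H2S_eps: 0.1
  warn_fraction: 0.8
evap:
  rhout_cutoff: 80
emergency:
  blind_mode: fixed
  blind_pos: 4
saf_tolerance: 0.1
dt3_max: 3
heater_gain: 20
prep:
  tpmin: 28
  tpmax: 32
  purge_s: 60
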
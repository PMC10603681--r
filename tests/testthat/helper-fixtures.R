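# Shared fixtures: packaged comfort grids and the reference replay config.
.fixture_env <- new.env()

test_tables <- function() {
  if (is.null(.fixture_env$ct)) .fixture_env$ct <- comfort_tables()
  .fixture_env$ct
}

reference_config <- function() {
  if (is.null(.fixture_env$cfg)) {
    .fixture_env$cfg <- read_config(reference_fixture("config"))
  }
  .fixture_env$cfg
}

# constant-conditions frame source for cycle-level tests
const_frames <- function(ti = 24.5, to = 10, tih = 25, RH = 72, RHout = 60,
                         dp = 25, SAF = 0.25, NH3 = 0, CO2 = 500, CO = 0,
                         H2S = 0) {
  function(t) list(t = t, ti = ti, to = to, tih = tih, RH = RH,
                   RHout = RHout, dp = dp, SAF = SAF, NH3 = NH3, CO2 = CO2,
                   CO = CO, H2S = H2S)
}

# step through a trace tick by tick collecting every actuator snapshot
audit_run <- function(trace, cfg, tables, until = max(trace$t)) {
  fs <- frame_source(trace)
  state <- init_controller_state(cfg)
  snaps <- list()
  for (t in seq(0, until, by = cfg$tick)) {
    r <- controller_step(state, fs(t), cfg, tables)
    state <- r$state
    snaps[[length(snaps) + 1L]] <- c(list(t = t, mode = state$mode,
                                          emergency = state$emergency),
                                     r$actuators)
  }
  snaps
}
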
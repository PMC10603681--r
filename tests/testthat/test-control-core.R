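ct <- test_tables()
cfg5 <- reference_config()

test_that("mode classification partitions the temperature axis", {
  sp <- setpoints(14, ct)
  expect_equal(classify_mode(22, sp), "M1")
  expect_equal(classify_mode(25, sp), "M2")
  expect_equal(classify_mode(26, sp), "TR")
  expect_equal(classify_mode(28, sp), "TU")
  # every temperature lands in exactly one branch, ordered with ti
  set.seed(5)
  for (ti in runif(200, 10, 40)) {
    m <- classify_mode(ti, sp)
    expect_true(m %in% c("M1", "M2", "TR", "TU"))
    expect_equal(m, c("M1", "M2", "TR", "TU")[
      findInterval(ti, c(sp$tmin, sp$topt, sp$tmax), left.open = TRUE) + 1])
  }
})

test_that("gas status warns at 80% of a limit and flags violations", {
  cfg <- controller_config()
  fr <- function(...) utils::modifyList(list(NH3 = 0, CO2 = 0, CO = 0,
                                             H2S = 0), list(...))
  expect_equal(gas_status(fr(), cfg$gas)$status, "NORMAL")
  expect_equal(gas_status(fr(CO2 = 2500), cfg$gas)$status, "WARN")
  expect_equal(gas_status(fr(CO2 = 2399), cfg$gas)$status, "NORMAL")
  ex <- gas_status(fr(CO2 = 3500), cfg$gas)
  expect_equal(ex$status, "EXCEED")
  expect_equal(ex$offending, "CO2")
  expect_match(ex$detail, "3500")
  expect_match(ex$detail, "3000")
  expect_equal(gas_status(fr(NH3 = 15), cfg$gas)$status, "EXCEED")
  expect_equal(gas_status(fr(NH3 = 12), cfg$gas)$status, "WARN")
  expect_equal(gas_status(fr(CO = 4.4), cfg$gas)$status, "EXCEED")
  # hydrogen sulfide: any detectable amount is a violation
  expect_equal(gas_status(fr(H2S = 0.2), cfg$gas)$status, "EXCEED")
  expect_equal(gas_status(fr(H2S = 0.05), cfg$gas)$status, "NORMAL")
  expect_error(gas_status(fr(CO2 = -1), cfg$gas), "nonnegative")
})

test_that("blind position lookup follows the reference map and clamps", {
  expect_equal(blind_position(17, 14, 20000, cfg5), 2L)
  expect_equal(blind_position(7, 14, 20000, cfg5), 3L)
  expect_equal(blind_position(10, 14, 20000, cfg5), 3L)
  expect_equal(blind_position(-5, 14, 20000, cfg5), 5L)
  # default two-column map: heavier flock gets one step more opening
  cfg <- controller_config()
  expect_gte(blind_position(8, 42, 20000, cfg),
             blind_position(8, 7, 20000, cfg))
  bad <- cfg
  bad$blinds$positions <- matrix(numeric(0), nrow = 0)
  expect_error(blind_position(5, 14, 20000, bad), "empty")
})

test_that("heater law reproduces the reference behaviour", {
  cfg <- controller_config()
  expect_equal(heater_power(5, "M1", FALSE, cfg), 100)
  expect_equal(heater_power(0.5, "M2", FALSE, cfg), 10)
  expect_equal(heater_power(0.5, "M2", TRUE, cfg), 50)
  expect_equal(heater_power(4, "M2", TRUE, cfg), 80)  # above the floor
  expect_equal(heater_power(-1, "M2", FALSE, cfg), 0)
  expect_equal(heater_power(10, "M2", FALSE, cfg), 100)
  expect_error(heater_power(1, "TR", FALSE, cfg), "M1/M2")
})

test_that("differential pressure regulation steps toward the band", {
  cfg <- controller_config()
  r <- regulate_dp(20, 40, cfg)
  expect_true(r$in_band)
  expect_equal(r$power, 40)
  low <- regulate_dp(10, 40, cfg)
  expect_false(low$in_band)
  expect_gt(low$power, 40)
  high <- regulate_dp(45, 40, cfg)
  expect_lt(high$power, 40)
  # a stuck pressure exhausts the iteration budget and faults
  p <- 40; i <- 0
  repeat {
    r <- regulate_dp(5, p, cfg, iter = i)
    if (r$fault || r$in_band) break
    p <- r$power; i <- i + 1
  }
  expect_true(r$fault)
  expect_equal(i + 1, cfg$dp$max_iter)
})

test_that("minimum ventilation cycle runs the duty-cycle sequence", {
  fs <- const_frames(ti = 25, to = 10, tih = 29)  # dt3 = 4 > 3
  r <- run_min_vent_cycle(init_controller_state(cfg5), fs, cfg5, ct)
  ev <- do.call(rbind, lapply(r$events, as.data.frame))
  on_t <- ev$t[ev$name == "vent_power" & ev$value != "0"][1]
  off_t <- ev$t[ev$name == "vent_power" & ev$value == "0"][1]
  expect_equal(off_t - on_t, cfg5$timers$ts3)          # 30 s pulse
  expect_equal(ev$value[ev$name == "heater"][1], "10") # M2 trim at dt2=0.5+
  expect_equal(ev$t[ev$name == "circ_fan" & ev$value == "1"][1], off_t)
  expect_equal(ev$value[ev$kind == "mode" & ev$name == "mode"][1], "M2")
})

test_that("persistent humidity excursions retune ts3 within its bounds", {
  # dry air: ts3 shrinks one step per cycle down to the lower bound
  fs <- const_frames(ti = 24.5, RH = 60)
  st <- init_controller_state(cfg5)
  seen <- numeric()
  for (k in 1:8) {
    r <- run_min_vent_cycle(st, fs, cfg5, ct)
    st <- r$state
    seen <- c(seen, st$ts3_cur)
  }
  # state is observed at the start of the following cycle, after the
  # adjustment has been applied
  expect_equal(seen[1:5], c(25, 20, 15, 10, 10))
  expect_true(all(seen >= cfg5$timers$ts3_bounds[1]))
  expect_true(all(diff(seen) <= 0))
  # humid air pushes it up to the upper bound
  st2 <- init_controller_state(cfg5)
  for (k in 1:10) {
    st2 <- run_min_vent_cycle(st2, const_frames(ti = 24.5, RH = 90),
                              cfg5, ct)$state
  }
  expect_equal(st2$ts3_cur, cfg5$timers$ts3_bounds[2])
})

test_that("humidity messages are one-time per episode", {
  fs <- const_frames(ti = 24.5, RH = 60)
  st <- init_controller_state(cfg5)
  events <- list()
  for (k in 1:4) {
    r <- run_min_vent_cycle(st, fs, cfg5, ct)
    st <- r$state
    events <- c(events, r$events)
  }
  ev <- do.call(rbind, lapply(events, as.data.frame))
  expect_equal(sum(ev$name == "rh_low"), 1)
})

test_that("a gas violation forces a 3-minute emergency cycle with full airing", {
  fs <- const_frames(ti = 24.5, CO2 = 3500)
  st <- init_controller_state(cfg5)
  r <- run_min_vent_cycle(st, fs, cfg5, ct)
  ev <- do.call(rbind, lapply(r$events, as.data.frame))
  expect_equal(r$state$cycle_start, 180)          # next cycle began at 3 min
  expect_true(any(ev$name == "gas_exceed"))
  expect_true(any(ev$name == "emergency" & ev$value == "1"))
  # ventilation ran the whole cycle: no shutoff before the boundary
  offs <- ev$t[ev$name == "vent_power" & ev$value == "0"]
  expect_true(all(offs >= 180))
  # fixture maps the emergency opening to position 4
  expect_equal(ev$value[ev$name == "blind_pos"][1], "4")
  # default config: flowchart behaviour, blinds to maximum in M2
  cfgd <- controller_config(timers = list(ts2 = 5))
  rd <- run_min_vent_cycle(init_controller_state(cfgd), fs, cfgd, ct)
  evd <- do.call(rbind, lapply(rd$events, as.data.frame))
  expect_equal(evd$value[evd$name == "blind_pos"][1],
               as.character(cfgd$n_positions))
  # in M1 the blinds open only two steps more, sparing the young birds
  fs_m1 <- const_frames(ti = 22, to = 15, CO2 = 3500)  # base position 3
  rm1 <- run_min_vent_cycle(init_controller_state(cfgd), fs_m1, cfgd, ct)
  evm1 <- do.call(rbind, lapply(rm1$events, as.data.frame))
  expect_equal(evm1$value[evm1$name == "blind_pos"][1], "4")  # X=2 plus 2
  expect_equal(evm1$value[evm1$name == "heater"][1], "100")
})

test_that("emergency alerts latch per episode and re-arm after recovery", {
  co2 <- function(t) {
    if (t < 300) 3500 else if (t < 900) 500 else if (t < 1200) 3500 else 500
  }
  fs <- function(t) list(t = t, ti = 24.5, to = 10, tih = 25, RH = 72,
                         RHout = 60, dp = 25, SAF = 0.25, NH3 = 0,
                         CO2 = co2(t), CO = 0, H2S = 0)
  st <- init_controller_state(cfg5)
  events <- list()
  t <- 0
  while (t <= 1500) {
    r <- controller_step(st, fs(t), cfg5, ct)
    st <- r$state
    events <- c(events, r$events)
    t <- t + cfg5$tick
  }
  ev <- do.call(rbind, lapply(events, as.data.frame))
  expect_equal(sum(ev$name == "gas_exceed"), 2)
  em <- ev[ev$name == "emergency", ]
  expect_equal(em$value, c("1", "0", "1", "0"))
})

test_that("transitional cycle ventilates continuously without regulation", {
  fs <- const_frames(ti = 26, to = 15, tih = 31, RH = 60)
  st <- init_controller_state(cfg5)
  r <- run_transitional_cycle(st, fs, cfg5, ct)
  ev <- do.call(rbind, lapply(r$events, as.data.frame))
  expect_equal(ev$value[ev$kind == "mode" & ev$name == "mode"], "TR")
  expect_equal(ev$value[ev$name == "blind_pos"][1], "4")  # map + TR offset
  expect_false(any(ev$name == "vent_power" & ev$value == "0"))
  expect_false(any(ev$name == "circ_fan" & ev$value == "1"))
  expect_false(any(ev$name == "heater" & ev$value != "0"))
  # humidity excursion: message only, no ts3 change
  expect_true(any(ev$name == "rh_low"))
  expect_equal(r$state$ts3_next, cfg5$timers$ts3)
})

test_that("time must not run backwards", {
  st <- init_controller_state(cfg5)
  r <- controller_step(st, const_frames()(0), cfg5, ct)
  r <- controller_step(r$state, const_frames()(1), cfg5, ct)
  expect_error(controller_step(r$state, const_frames()(0.5), cfg5, ct),
               "backwards")
})

test_that("building preparation purges then thermostats the band", {
  cfg <- controller_config(timers = list(ts2 = 5))
  st <- init_controller_state(cfg, mode = "PREP")
  # purge cycle ventilates at full power regardless of temperature
  r <- run_prep(st, const_frames(ti = 30, to = 20), cfg, ct)
  ev <- do.call(rbind, lapply(r$events, as.data.frame))
  expect_equal(ev$value[ev$name == "vent_power"][1], "100")
  # cold building: heater on, no ventilation
  r2 <- run_prep(r$state, const_frames(ti = 20, to = 5), cfg, ct)
  ev2 <- do.call(rbind, lapply(r2$events, as.data.frame))
  expect_equal(ev2$value[ev2$name == "heater"][1], "100")
  expect_equal(r2$state$act$vent_power, 0)
  # hot building: ventilation cycle
  r3 <- run_prep(r2$state, const_frames(ti = 34, to = 20), cfg, ct)
  expect_gt(r3$state$act$vent_power, 0)
  expect_equal(r3$state$act$heater, 0)
  # in band: idle hold
  r4 <- run_prep(r3$state, const_frames(ti = 30, to = 20), cfg, ct)
  expect_equal(r4$state$act$heater, 0)
  expect_equal(r4$state$act$vent_power, 0)
  expect_equal(r4$state$mode, "PREP")
})
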
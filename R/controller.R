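#' Ventilation branch for a measured temperature
#'
#' Partition of the temperature axis into the controller's branches:
#' below the comfort band heating-dominated minimum ventilation (M1), from
#' \code{tmin} to the optimum heat-trimming minimum ventilation (M2), from
#' the optimum to \code{tmax} transitional ventilation (TR), above the band
#' tunnel ventilation (TU). Exactly one branch matches any temperature.
#'
#' @param ti indoor temperature at bird level, deg C.
#' @param sp a [setpoints()] object.
#' @return one of \code{"M1"}, \code{"M2"}, \code{"TR"}, \code{"TU"}.
#' @export
classify_mode <- function(ti, sp) {
  if (ti < sp$tmin) "M1"
  else if (ti <= sp$topt) "M2"
  else if (ti <= sp$tmax) "TR"
  else "TU"
}

#' Harmful-gas status of a sensor frame
#'
#' A gas at or above its permissible limit (for H2S, any reading above the
#' detection floor) is a violation; a gas at or above the pre-warning
#' fraction of its limit is a warning.
#'
#' @param frame sensor frame (list/row with \code{NH3}, \code{CO2},
#'   \code{CO}, \code{H2S} in ppm).
#' @param limits the \code{gas} element of a [controller_config()].
#' @return list with \code{status} (\code{"NORMAL"}, \code{"WARN"} or
#'   \code{"EXCEED"}), \code{offending} (gas names driving the status) and
#'   \code{detail} (human-readable measurement vs limit).
#' @export
gas_status <- function(frame, limits) {
  vals <- c(NH3 = frame$NH3, CO2 = frame$CO2, CO = frame$CO,
            H2S = frame$H2S)
  if (any(vals < 0)) stop("gas readings must be nonnegative")
  lims <- c(NH3 = limits$NH3_max, CO2 = limits$CO2_max, CO = limits$CO_max,
            H2S = limits$H2S_eps)
  exceed <- c(vals[1:3] >= lims[1:3], vals[4] > lims[4])
  warn <- c(vals[1:3] >= limits$warn_fraction * lims[1:3], FALSE)
  status <- if (any(exceed)) "EXCEED" else if (any(warn)) "WARN" else "NORMAL"
  off <- names(vals)[if (any(exceed)) exceed else warn]
  detail <- paste(sprintf("%s %g ppm (limit %g)", off, vals[off], lims[off]),
                  collapse = "; ")
  list(status = status, offending = off, detail = detail)
}

#' Blind opening position from the temperature difference and flock weight
#'
#' Two-dimensional step lookup: the indoor-outdoor difference dt1 selects
#' the row (colder outside means a smaller opening), the total live weight
#' of the flock the column. The result is clamped to the configured range.
#'
#' @param dt1 indoor minus outdoor temperature, deg C.
#' @param ts1 flock age in days.
#' @param N number of birds.
#' @param cfg a [controller_config()].
#' @return integer blind position in \code{[1, n_positions]}.
#' @export
blind_position <- function(dt1, ts1, N, cfg) {
  b <- cfg$blinds
  if (length(b$positions) == 0) stop("blind position map is empty")
  i <- findInterval(dt1, b$dt1_breaks) + 1
  j <- if (length(b$weight_breaks) == 0) 1 else
    findInterval(N * broiler_weight(ts1), b$weight_breaks) + 1
  j <- min(j, ncol(b$positions))
  as.integer(clamp(b$positions[i, j], 1, cfg$n_positions))
}

#' Heater output for the minimum-ventilation branches
#'
#' In M1 heating always runs at full power. In M2 the output is
#' proportional to the deficit below the optimum temperature
#' (\code{heater_gain} percent per deg C); during a gas emergency it is at
#' least 50\% so the extra airing does not chill the flock.
#'
#' @param dt2 topt minus measured ti, deg C.
#' @param mode \code{"M1"} or \code{"M2"}.
#' @param emergency logical.
#' @param cfg a [controller_config()].
#' @return heater output percent in \code{[0, 100]}.
#' @export
heater_power <- function(dt2, mode, emergency = FALSE, cfg) {
  if (!mode %in% c("M1", "M2")) stop("heater runs only in M1/M2")
  if (mode == "M1") return(100)
  p <- clamp(cfg$heater_gain * dt2, 0, 100)
  if (emergency) p <- max(p, 50)
  p
}

#' One proportional differential-pressure correction step
#'
#' Leaves the fan power unchanged inside the operating band; otherwise
#' steps it toward the band midpoint. The caller counts steps per cycle;
#' once \code{dp$max_iter} corrections have not brought the pressure into
#' band a fault is flagged (fouled blinds or fan outlets).
#'
#' @param measured_dp differential pressure, Pa.
#' @param vent_power current fan power, percent.
#' @param cfg a [controller_config()].
#' @param iter corrections already applied this cycle.
#' @return list with \code{power}, \code{in_band}, \code{fault}.
#' @export
regulate_dp <- function(measured_dp, vent_power, cfg, iter = 0) {
  band <- cfg$dp$band
  if (measured_dp >= band[1] && measured_dp <= band[2]) {
    return(list(power = vent_power, in_band = TRUE, fault = FALSE))
  }
  target <- mean(band)
  power <- clamp(vent_power + cfg$dp$gain * (target - measured_dp), 0, 100)
  list(power = power, in_band = FALSE, fault = iter + 1 >= cfg$dp$max_iter)
}

#' Fresh controller state
#'
#' @param cfg a [controller_config()].
#' @param mode starting mode; \code{NA} lets the first cycle classify from
#'   the measured temperature, \code{"PREP"} starts building preparation.
#' @return object of class \code{controller_state}.
#' @export
init_controller_state <- function(cfg, mode = NA_character_) {
  structure(list(
    t = NA_real_, mode = mode, emergency = FALSE,
    cycle_start = NA_real_, cycle_len = NA_real_,
    ts3_cur = cfg$timers$ts3, ts3_next = cfg$timers$ts3,
    act = list(heater = 0, blind_pos = 0L, vent_power = 0,
               circ_fan = FALSE, tunnel_inlets = FALSE, tunnel_power = 0,
               evap_pads = FALSE),
    latched = character(), seen = character(),
    dp_iter = 0L, saf_iter = 0L,
    vent_stopped = TRUE, vent_off_at = Inf,
    dp_reg = FALSE, saf_reg = FALSE, rh_regulate = FALSE,
    saf_set = NA_real_, pads_ok_t = -Inf, prep_purged = FALSE),
    class = "controller_state")
}

fmt_value <- function(v) {
  if (is.logical(v)) as.character(as.integer(v)) else as.character(v)
}

#' Advance the controller by one clock tick
#'
#' The per-tick primitive behind every branch. At cycle boundaries the
#' indoor temperature is re-measured and the branch re-selected (except in
#' the evaporative-cooling closed cycle, which watches only the felt
#' temperature); within a cycle the differential pressure or tunnel air
#' speed is regulated and the duty-cycle timers run down. One-time messages
#' are emitted once per condition episode; the latch clears after a full
#' cycle in which the condition is absent.
#'
#' @param state a [init_controller_state()] object.
#' @param frame sensor frame: list with \code{t} (s), \code{ti}, \code{to},
#'   \code{tih} (deg C), \code{RH}, \code{RHout} (percent), \code{dp} (Pa),
#'   \code{SAF} (m/s), \code{NH3}, \code{CO2}, \code{CO}, \code{H2S} (ppm).
#' @param cfg a [controller_config()].
#' @param tables a [comfort_tables()].
#' @return list with \code{state}, \code{actuators} and \code{events}
#'   (list of \code{t}/\code{kind}/\code{name}/\code{value} records).
#' @export
controller_step <- function(state, frame, cfg, tables) {
  if (!is.na(state$t) && frame$t < state$t) {
    stop("sensor frame time going backwards")
  }
  events <- list()
  emit <- function(kind, name, value) {
    events[[length(events) + 1L]] <<- list(t = frame$t, kind = kind,
                                           name = name,
                                           value = fmt_value(value))
  }
  set_act <- function(name, value) {
    if (!identical(state$act[[name]], value)) {
      state$act[[name]] <<- value
      emit("actuator", name, value)
    }
  }
  raise <- function(cond, value) {
    state$seen <<- union(state$seen, cond)
    if (!(cond %in% state$latched)) {
      state$latched <<- union(state$latched, cond)
      emit("alert", cond, value)
    }
  }
  note_mode <- function(m) {
    if (!identical(m, state$mode)) {
      state$mode <<- m
      emit("mode", "mode", m)
    }
  }
  set_emergency <- function(on) {
    if (!identical(state$emergency, on)) {
      state$emergency <<- on
      emit("mode", "emergency", on)
    }
  }
  age <- cfg$flock$age
  sp <- setpoints(age, tables)
  power_for <- function(pos) {
    if (pos <= 0) 0 else cfg$fans$power_map[min(pos, cfg$n_positions)]
  }
  saf_to_power <- function(z) clamp(100 * z / cfg$fans$tunnel_full_saf, 0, 100)

  gas_begin <- function(allow_emergency = TRUE) {
    gs <- gas_status(frame, cfg$gas)
    if (gs$status == "EXCEED") {
      raise("gas_exceed", gs$detail)
      if (allow_emergency) set_emergency(TRUE)
    } else if (allow_emergency) {
      set_emergency(FALSE)
    }
    gs
  }

  widened_blind <- function(x, gs, m) {
    if (state$emergency) {
      e <- cfg$emergency
      if (identical(m, "M1")) x + 2           # keep young birds warm
      else switch(e$blind_mode,
                  max = cfg$n_positions,
                  x_plus_2 = x + 2,
                  fixed = e$blind_pos)
    } else if (gs$status == "WARN") x + 1 else x
  }

  min_vent_begin <- function(m) {
    gs <- gas_begin()
    x <- blind_position(frame$ti - frame$to, age, cfg$flock$N, cfg)
    x <- as.integer(clamp(widened_blind(x, gs, m), 1, cfg$n_positions))
    state$cycle_len <<- if (state$emergency)
      cfg$timers$emergency_ts2 * 60 else cycle_time(cfg, age)
    set_act("tunnel_power", 0); set_act("tunnel_inlets", FALSE)
    set_act("evap_pads", FALSE); set_act("circ_fan", FALSE)
    set_act("heater",
            heater_power(sp$topt - frame$ti, m, state$emergency, cfg))
    set_act("blind_pos", x)
    set_act("vent_power", power_for(x))
    state$vent_off_at <<- if (state$emergency) Inf else state$ts3_cur
    state$vent_stopped <<- state$emergency  # emergency: no mid-cycle stop
    state$rh_regulate <<- !state$emergency
    state$dp_reg <<- TRUE; state$saf_reg <<- FALSE
  }

  tr_begin <- function() {
    gs <- gas_begin()
    x <- blind_position(frame$ti - frame$to, age, cfg$flock$N, cfg) +
      cfg$blinds$tr_offset
    x <- as.integer(clamp(widened_blind(x, gs, "TR"), 1, cfg$n_positions))
    state$cycle_len <<- if (state$emergency)
      cfg$timers$emergency_ts2 * 60 else cycle_time(cfg, age)
    set_act("tunnel_power", 0); set_act("tunnel_inlets", FALSE)
    set_act("evap_pads", FALSE); set_act("circ_fan", FALSE)
    set_act("heater", 0)
    set_act("blind_pos", x)
    set_act("vent_power", power_for(x))
    state$vent_off_at <<- Inf; state$vent_stopped <<- TRUE
    state$rh_regulate <<- FALSE
    state$dp_reg <<- TRUE; state$saf_reg <<- FALSE
  }

  tunnel_run <- function(z, evap) {
    set_act("heater", 0); set_act("vent_power", 0)
    set_act("blind_pos", 0L); set_act("circ_fan", FALSE)
    if (!evap) set_act("evap_pads", FALSE)
    set_act("tunnel_inlets", TRUE)
    set_act("tunnel_power", saf_to_power(z))
    if (evap) set_act("evap_pads", TRUE)
    state$saf_set <<- z
    state$cycle_len <<- 5 * 60
    state$vent_off_at <<- Inf; state$vent_stopped <<- TRUE
    state$rh_regulate <<- FALSE
    state$dp_reg <<- FALSE; state$saf_reg <<- TRUE
  }

  enter_shutdown <- function() {
    note_mode("EVAP_SHUTDOWN")
    set_act("evap_pads", FALSE)
    z <- optimal_airspeed(frame$ti, frame$RH, age, tables)$z
    tunnel_run(z, evap = FALSE)
    state$cycle_len <<- cfg$timers$ts_drying * 60
    state$pads_ok_t <<- frame$t + cfg$timers$ts_drying * 60
  }

  tunnel_begin <- function() {
    gas_begin(allow_emergency = FALSE)
    zmax <- max_airspeed(age, tables)
    tf <- as.numeric(felt_temperature(frame$ti, zmax, frame$RH, age, tables))
    if (tf < sp$tmin) {
      tunnel_run(optimal_airspeed(frame$ti, frame$RH, age, tables)$z,
                 evap = FALSE)
    } else if (tf <= sp$tmax) {
      tunnel_run(zmax, evap = FALSE)
    } else if (frame$RHout >= cfg$evap$rhout_cutoff ||
               frame$t < state$pads_ok_t) {
      tunnel_run(zmax, evap = FALSE)
    } else {
      note_mode("TU_EVAP")
      tunnel_run(zmax, evap = TRUE)
    }
  }

  evap_hold_cycle <- function() {
    gas_begin(allow_emergency = FALSE)
    zmax <- max_airspeed(age, tables)
    tf <- as.numeric(felt_temperature(frame$ti, zmax, frame$RH, age, tables))
    if (frame$RHout >= cfg$evap$rhout_cutoff || tf < sp$tmin) {
      enter_shutdown()
    } else if (tf > sp$tmax) {
      note_mode("TU_EVAP_HOLD")
      tunnel_run(zmax, evap = TRUE)
    } else {
      note_mode("TU_EVAP_HOLD")
      tunnel_run(optimal_airspeed(frame$ti, frame$RH, age, tables)$z,
                 evap = TRUE)
    }
  }

  prep_begin <- function() {
    note_mode("PREP")
    state$cycle_len <<- cycle_time(cfg, age)
    state$vent_off_at <<- Inf; state$vent_stopped <<- TRUE
    state$rh_regulate <<- FALSE; state$saf_reg <<- FALSE
    set_act("tunnel_power", 0); set_act("tunnel_inlets", FALSE)
    set_act("evap_pads", FALSE); set_act("circ_fan", FALSE)
    if (!state$prep_purged) {
      # initial airing to flush disinfection smells
      set_act("heater", 0)
      set_act("blind_pos", as.integer(cfg$n_positions))
      set_act("vent_power", 100)
      state$cycle_len <<- max(cfg$prep$purge_s, cfg$timers$ts3)
      state$prep_purged <<- TRUE
      state$dp_reg <<- FALSE
    } else if (frame$ti < cfg$prep$tpmin) {
      set_act("heater", 100); set_act("blind_pos", 0L)
      set_act("vent_power", 0); state$dp_reg <<- FALSE
    } else if (frame$ti > cfg$prep$tpmax) {
      x <- blind_position(frame$ti - frame$to, age, cfg$flock$N, cfg)
      set_act("heater", 0); set_act("blind_pos", x)
      set_act("vent_power", power_for(x)); state$dp_reg <<- TRUE
    } else {
      set_act("heater", 0); set_act("blind_pos", 0L)
      set_act("vent_power", 0); state$dp_reg <<- FALSE
    }
  }

  begin_cycle <- function() {
    state$cycle_start <<- frame$t
    state$dp_iter <<- 0L; state$saf_iter <<- 0L
    state$ts3_cur <<- state$ts3_next
    prev <- state$mode
    if (identical(prev, "PREP")) {
      prep_begin()
    } else if (identical(prev, "TU_EVAP") ||
               identical(prev, "TU_EVAP_HOLD")) {
      evap_hold_cycle()
    } else {
      m <- classify_mode(frame$ti, sp)
      if (m == "M1" && !identical(prev, "M1")) raise("m1_entry", frame$ti)
      note_mode(m)
      switch(m,
             M1 = min_vent_begin("M1"), M2 = min_vent_begin("M2"),
             TR = tr_begin(), TU = tunnel_begin())
    }
  }

  phase_tick <- function(el) {
    if (!state$vent_stopped && el >= state$vent_off_at) {
      set_act("vent_power", 0)
      set_act("blind_pos", 0L)
      set_act("circ_fan", frame$tih - frame$ti > cfg$dt3_max)
      state$vent_stopped <<- TRUE
    }
    if (state$dp_reg && state$act$vent_power > 0 && el >= cfg$timers$ts4) {
      r <- regulate_dp(frame$dp, state$act$vent_power, cfg,
                       iter = state$dp_iter)
      if (!r$in_band) {
        if (state$dp_iter < cfg$dp$max_iter) {
          set_act("vent_power", r$power)
          state$dp_iter <<- state$dp_iter + 1L
        } else {
          raise("dp_fault", sprintf("dp %g Pa outside %g-%g Pa", frame$dp,
                                    cfg$dp$band[1], cfg$dp$band[2]))
        }
      }
    }
    if (state$saf_reg && state$act$tunnel_power > 0 &&
        el >= cfg$timers$ts4 && !is.na(state$saf_set)) {
      dev <- abs(frame$SAF - state$saf_set)
      if (dev > cfg$saf_tolerance * state$saf_set) {
        if (state$saf_iter < cfg$dp$max_iter) {
          p <- clamp(state$act$tunnel_power *
                       state$saf_set / max(frame$SAF, 0.01), 0, 100)
          set_act("tunnel_power", p)
          state$saf_iter <<- state$saf_iter + 1L
        } else {
          raise("saf_fault", sprintf("SAF %g m/s vs set %g m/s", frame$SAF,
                                     state$saf_set))
        }
      }
    }
  }

  end_cycle <- function() {
    set_act("circ_fan", FALSE)
    if (state$mode %in% c("M1", "M2", "TR")) {
      low <- frame$RH < sp$rh_min
      high <- frame$RH > sp$rh_max
      if (low) raise("rh_low", frame$RH)
      if (high) raise("rh_high", frame$RH)
      if (state$rh_regulate) {
        tm <- cfg$timers
        step <- if (low) -tm$ts3_step else if (high) tm$ts3_step else 0
        state$ts3_next <<- clamp(state$ts3_cur + step,
                                 tm$ts3_bounds[1], tm$ts3_bounds[2])
      }
    }
    state$latched <<- intersect(state$latched, state$seen)
    state$seen <<- character()
  }

  if (is.na(state$cycle_start)) {
    begin_cycle()
  } else {
    el <- frame$t - state$cycle_start
    if (el >= state$cycle_len) {
      end_cycle()
      begin_cycle()
    } else {
      phase_tick(el)
    }
  }
  state$t <- frame$t
  list(state = state, actuators = state$act, events = events)
}

#' @export
print.controller_state <- function(x, ...) {
  cat(sprintf("<controller_state> t=%s mode=%s%s blind=%d vent=%g%% heater=%g%%\n",
              format(x$t), ifelse(is.na(x$mode), "?", x$mode),
              if (isTRUE(x$emergency)) " [EMERGENCY]" else "",
              x$act$blind_pos, x$act$vent_power, x$act$heater))
  invisible(x)
}
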
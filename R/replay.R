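#' Sample-and-hold frame source from a sensor trace
#'
#' Returns a function of time producing the most recent trace row at or
#' before that time (readings are held between updates, as with a broker
#' that re-publishes values on change).
#'
#' @param trace data.frame in canonical trace form (see [read_trace()]).
#' @return function \code{(t) -> frame} (a list, with \code{t} replaced by
#'   the query time).
#' @export
frame_source <- function(trace) {
  force(trace)
  function(t) {
    i <- findInterval(t, trace$t)
    if (i < 1) i <- 1
    fr <- as.list(trace[i, ])
    fr$t <- t
    fr
  }
}

run_cycle_impl <- function(state, frame_source, cfg, tables, allowed) {
  t0 <- if (is.na(state$t)) 0 else state$t + cfg$tick
  events <- list()
  r <- controller_step(state, frame_source(t0), cfg, tables)
  state <- r$state; events <- c(events, r$events)
  if (!is.na(allowed[1]) && !state$mode %in% allowed) {
    stop("controller selected branch ", state$mode, ", expected one of ",
         paste(allowed, collapse = "/"))
  }
  cycle_end <- state$cycle_start + state$cycle_len
  t <- t0
  while (t + cfg$tick <= cycle_end) {
    t <- t + cfg$tick
    r <- controller_step(state, frame_source(t), cfg, tables)
    state <- r$state; events <- c(events, r$events)
  }
  list(state = state, events = events)
}

#' Run one minimum-ventilation cycle
#'
#' Executes a full M1/M2 duty cycle tick by tick against a frame source:
#' gas check, heater and blind setting, ventilation pulse with
#' differential-pressure regulation, stratification-driven circulation fan,
#' and the end-of-cycle humidity check that retunes the next ventilation-on
#' time. The returned state sits at the start of the following cycle.
#'
#' @param state a [init_controller_state()] (mode unset, M1 or M2).
#' @param frame_source function \code{(t) -> frame}, see [frame_source()].
#' @param cfg a [controller_config()].
#' @param tables a [comfort_tables()].
#' @return list with \code{state} and \code{events}.
#' @export
run_min_vent_cycle <- function(state, frame_source, cfg, tables) {
  run_cycle_impl(state, frame_source, cfg, tables, c("M1", "M2"))
}

#' Run one transitional-ventilation cycle
#'
#' Continuous ventilation through wider-open blinds, heater and circulation
#' fans off; humidity excursions are reported but not acted on.
#'
#' @inheritParams run_min_vent_cycle
#' @return list with \code{state} and \code{events}.
#' @export
run_transitional_cycle <- function(state, frame_source, cfg, tables) {
  run_cycle_impl(state, frame_source, cfg, tables, "TR")
}

#' Run one tunnel-ventilation cycle
#'
#' Felt-temperature-driven tunnel airflow with air-speed correction, the
#' evaporative-cooling branch with its outdoor-humidity cutoff, the closed
#' monitoring cycle while pads are wet, and the pad-drying shutdown.
#'
#' @inheritParams run_min_vent_cycle
#' @return list with \code{state} and \code{events}.
#' @export
run_tunnel_cycle <- function(state, frame_source, cfg, tables) {
  run_cycle_impl(state, frame_source, cfg, tables,
                 c("TU", "TU_EVAP", "TU_EVAP_HOLD", "EVAP_SHUTDOWN"))
}

#' Run one building-preparation cycle
#'
#' Initial airing purge, then a thermostat holding the empty building
#' within the preparation band so the litter warms before the chicks are
#' housed.
#'
#' @inheritParams run_min_vent_cycle
#' @return list with \code{state} and \code{events}.
#' @export
run_prep <- function(state, frame_source, cfg, tables) {
  if (!identical(state$mode, "PREP")) {
    stop("state must be initialised with mode = \"PREP\"")
  }
  if (is.na(cfg$prep$tpmin) || is.na(cfg$prep$tpmax)) {
    stop("preparation band tpmin/tpmax must be configured")
  }
  run_cycle_impl(state, frame_source, cfg, tables, "PREP")
}

events_to_df <- function(events) {
  if (length(events) == 0) {
    return(data.frame(t = numeric(), kind = character(),
                      name = character(), value = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    t = vapply(events, function(e) as.numeric(e$t), numeric(1)),
    kind = vapply(events, function(e) e$kind, character(1)),
    name = vapply(events, function(e) e$name, character(1)),
    value = vapply(events, function(e) e$value, character(1)),
    stringsAsFactors = FALSE)
}

#' Replay a sensor trace through the controller
#'
#' Feeds a recorded (or synthesised) sensor trace to the controller tick by
#' tick with sample-and-hold between rows and collects the event log.
#' Identical trace and configuration give an identical log.
#'
#' @param trace canonical sensor-trace data.frame (see [read_trace()]).
#' @param cfg a [controller_config()].
#' @param tables a [comfort_tables()]; defaults to the packaged grids.
#' @param until final time in s; defaults to the last trace row plus one
#'   nominal cycle so the closing cycle boundary is observed.
#' @param state starting state; defaults to a fresh controller.
#' @return list with \code{events} (data.frame \code{t}, \code{kind},
#'   \code{name}, \code{value}) and the final \code{state}.
#' @export
replay_trace <- function(trace, cfg, tables = comfort_tables(),
                         until = NULL, state = NULL) {
  fs <- frame_source(trace)
  if (is.null(until)) until <- max(trace$t) + cycle_time(cfg)
  if (is.null(state)) state <- init_controller_state(cfg)
  events <- vector("list", 256L); n <- 0L
  for (t in seq(0, until, by = cfg$tick)) {
    r <- controller_step(state, fs(t), cfg, tables)
    state <- r$state
    for (e in r$events) {
      n <- n + 1L
      if (n > length(events)) events <- c(events, vector("list", length(events)))
      events[[n]] <- e
    }
  }
  list(events = events_to_df(events[seq_len(n)]), state = state)
}
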
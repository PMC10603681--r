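#' Default broiler growth curve
#'
#' Gompertz body-mass curve calibrated to reach 2 kg at 35 days (about 40 g
#' at hatch). A stand-in for breed-specific curves; replace via
#' [flock_params()].
#'
#' @param age days.
#' @return mass in kg per bird.
#' @export
broiler_weight <- function(age) {
  5 * exp(-5.27 * exp(-0.05 * age))
}

#' Flock parameters for the plant model
#'
#' @param N number of birds.
#' @param age days.
#' @param weight_curve function days -> kg/bird; must be nondecreasing.
#' @param heat_rate sensible+latent heat production, kJ/h per kg live
#'   weight (literature average 11.6).
#' @param water_rate evaporated water, L/day, for the 40-tonne reference
#'   flock (20,000 birds at 2 kg); scaled by actual live weight.
#' @param co2_rate CO2 exhalation, m3/h per kg live weight.
#' @return object of class \code{flock_params}.
#' @export
flock_params <- function(N = 20000, age = 14, weight_curve = broiler_weight,
                         heat_rate = 11.6, water_rate = 4000,
                         co2_rate = 8e-4) {
  if (heat_rate <= 0) stop("heat_rate must be positive")
  w <- weight_curve(c(1, 10, 20, 40))
  if (any(diff(w) < 0)) stop("weight_curve must be nondecreasing")
  structure(list(N = N, age = age, weight_curve = weight_curve,
                 heat_rate = heat_rate, water_rate = water_rate,
                 co2_rate = co2_rate), class = "flock_params")
}

#' Building parameters for the plant model
#'
#' Lumped single-zone description of the house. All values are invented,
#' physically plausible defaults for a medium 20,000-bird house and are
#' meant to be replaced with per-building data.
#'
#' @param volume air volume, m3.
#' @param envelope_UA envelope heat-loss coefficient, W per deg C.
#' @param cross_section tunnel flow cross-section, m2.
#' @param blind_area_per_pos inlet area added per blind position, m2.
#' @param tunnel_inlet_area total tunnel-inlet area, m2.
#' @param fan_max_flow ventilation-fan flow at 100 percent, m3/h.
#' @param tunnel_max_flow tunnel-fan flow at 100 percent, m3/h.
#' @param heater_capacity kW at 100 percent.
#' @param evap_effectiveness wet-bulb approach fraction of the pads, 0..1.
#' @param orifice_k inlet orifice pressure coefficient, Pa per (m/s)^2.
#' @param dp_max cap on modelled differential pressure, Pa.
#' @param strat_max ceiling-floor temperature offset with still air, deg C.
#' @param strat_tau stratification time constant, s.
#' @return object of class \code{building_params}.
#' @export
building_params <- function(volume = 12000, envelope_UA = 2000,
                            cross_section = 100, blind_area_per_pos = 0.5,
                            tunnel_inlet_area = 60, fan_max_flow = 60000,
                            tunnel_max_flow = 1.08e6, heater_capacity = 150,
                            evap_effectiveness = 0.75, orifice_k = 1.4,
                            dp_max = 60, strat_max = 3.5, strat_tau = 300) {
  vals <- c(volume, envelope_UA, cross_section, blind_area_per_pos,
            tunnel_inlet_area, fan_max_flow, tunnel_max_flow,
            heater_capacity, orifice_k, dp_max, strat_tau)
  if (any(vals <= 0)) stop("building parameters must be positive")
  if (evap_effectiveness < 0 || evap_effectiveness > 1) {
    stop("evap_effectiveness must lie in [0, 1]")
  }
  structure(as.list(environment()), class = "building_params")
}

#' Metabolic heat output of the flock
#'
#' @param N birds.
#' @param w mean live weight, kg/bird.
#' @param heat_rate kJ/h/kg.
#' @return kW.
#' @export
#' @examples
#' flock_heat(20000, 2)  # about 130 kW
flock_heat <- function(N, w, heat_rate = 11.6) {
  if (N < 0 || w < 0) stop("N and w must be nonnegative")
  N * w * heat_rate / 3600
}

#' Differential pressure from an orifice model
#'
#' Static-pressure drop across the inlets for a given extract flow:
#' \code{dp = k (Q/A)^2} with the face velocity in m/s: monotone increasing
#' in flow, quadratically decreasing in open area. With no open area and
#' nonzero flow the result is capped at \code{dp_max} and flagged as a
#' fault.
#'
#' @param vent_flow extract flow, m3/h.
#' @param open_area inlet area, m2.
#' @param k orifice coefficient, Pa per (m/s)^2.
#' @param dp_max cap, Pa.
#' @return dp in Pa, with logical attribute \code{fault}.
#' @export
pressure_model <- function(vent_flow, open_area, k = 1.4, dp_max = 60) {
  if (vent_flow == 0) {
    dp <- 0; fault <- FALSE
  } else if (open_area <= 0) {
    dp <- dp_max; fault <- TRUE
  } else {
    v <- vent_flow / 3600 / open_area
    dp <- k * v^2
    fault <- dp > dp_max
    dp <- min(dp, dp_max)
  }
  structure(dp, fault = fault)
}

sat_mixing_ratio <- function(t) {
  es <- 610.94 * exp(17.625 * t / (t + 243.04))  # Pa, Magnus
  0.622 * es / (101325 - es)
}

#' Initial plant state
#'
#' @param ti indoor temperature, deg C.
#' @param RH indoor relative humidity, percent.
#' @param CO2 ppm.
#' @param strat ceiling-floor offset, deg C.
#' @return object of class \code{plant_state} with fields \code{ti},
#'   \code{tih}, \code{RH}, \code{CO2}, \code{dp}, \code{SAF} and the
#'   internal moisture mixing ratio \code{x}.
#' @export
plant_state <- function(ti = 20, RH = 60, CO2 = 500, strat = 2) {
  structure(list(ti = ti, tih = ti + strat, RH = RH, CO2 = CO2,
                 dp = 0, SAF = 0.25,
                 x = RH / 100 * sat_mixing_ratio(ti)),
            class = "plant_state")
}

#' Advance the simulated building by one time step
#'
#' Explicit-Euler update of a first-order heat, moisture and CO2 balance:
#' flock and heater power against envelope losses and ventilation air
#' exchange; evaporative pads pull the supply air toward a crude wet bulb;
#' humidity and CO2 follow source-minus-dilution dynamics; the under-roof
#' temperature relaxes to a stratification offset that collapses when the
#' circulation fans run; differential pressure from the orifice model and
#' tunnel air speed from the flow over the house cross-section.
#'
#' @param state a [plant_state()].
#' @param act actuator list as produced by the controller
#'   (\code{heater}, \code{blind_pos}, \code{vent_power}, \code{circ_fan},
#'   \code{tunnel_inlets}, \code{tunnel_power}, \code{evap_pads}).
#' @param weather list with \code{to} (deg C) and \code{RHout} (percent).
#' @param flock a [flock_params()].
#' @param bldg a [building_params()].
#' @param dt time step, s (> 0).
#' @return updated \code{plant_state}.
#' @export
plant_step <- function(state, act, weather, flock, bldg, dt) {
  if (dt <= 0) stop("dt must be positive")
  rho_cp <- 1.2 * 1005                      # J/m3/K
  w <- flock$weight_curve(flock$age)
  live <- flock$N * w
  p_flock <- flock_heat(flock$N, w, flock$heat_rate) * 1000   # W
  p_heat <- act$heater / 100 * bldg$heater_capacity * 1000    # W
  q_vent <- act$vent_power / 100 * bldg$fan_max_flow / 3600   # m3/s
  q_tun <- if (act$tunnel_inlets)
    act$tunnel_power / 100 * bldg$tunnel_max_flow / 3600 else 0
  q <- q_vent + q_tun
  t_sup <- weather$to
  if (isTRUE(act$evap_pads) && q_tun > 0) {
    twb <- weather$to - (100 - weather$RHout) / 5   # crude wet-bulb approach
    t_sup <- weather$to - bldg$evap_effectiveness * (weather$to - twb)
  }
  cap <- rho_cp * bldg$volume                                 # J/K
  dti <- (p_flock + p_heat - bldg$envelope_UA * (state$ti - weather$to) -
            rho_cp * q * (state$ti - t_sup)) / cap * dt
  ti <- state$ti + dti
  # CO2 (ppm): exhalation source vs dilution toward ambient
  amb <- 420
  co2 <- state$CO2 +
    (live * flock$co2_rate / 3600 / bldg$volume * 1e6 -
       q / bldg$volume * (state$CO2 - amb)) * dt
  co2 <- max(co2, amb)
  # moisture mixing ratio (kg/kg)
  evap_src <- flock$water_rate * (live / 40000) / 86400       # kg/s
  x_out <- weather$RHout / 100 * sat_mixing_ratio(weather$to)
  x <- state$x + (evap_src / (1.2 * bldg$volume) -
                    q / bldg$volume * (state$x - x_out)) * dt
  x <- max(x, 1e-5)
  rh <- clamp(100 * x / sat_mixing_ratio(ti), 1, 100)
  # stratification
  target <- if (isTRUE(act$circ_fan)) 0.3 else bldg$strat_max
  off <- (state$tih - state$ti) +
    (target - (state$tih - state$ti)) * dt / bldg$strat_tau
  # pressure and air speed
  open_area <- act$blind_pos * bldg$blind_area_per_pos +
    (if (act$tunnel_inlets) bldg$tunnel_inlet_area else 0)
  dp <- as.numeric(pressure_model(q * 3600, open_area, bldg$orifice_k,
                                  bldg$dp_max))
  saf <- if (act$tunnel_inlets && q_tun > 0) q_tun / bldg$cross_section
  else 0.25
  structure(list(ti = ti, tih = ti + off, RH = rh, CO2 = co2, dp = dp,
                 SAF = saf, x = x), class = "plant_state")
}

#' Closed-loop simulation of controller plus building
#'
#' Runs the controller against the simulated plant: each tick the plant
#' state is read as a sensor frame, the controller acts, and the plant
#' integrates the actuator effects under the supplied weather.
#'
#' @param cfg a [controller_config()].
#' @param tables a [comfort_tables()].
#' @param flock a [flock_params()] (defaults to the configured flock).
#' @param bldg a [building_params()].
#' @param weather function \code{(t) -> list(to, RHout)}.
#' @param duration_s simulated time, s.
#' @param init initial [plant_state()].
#' @param record_every sampling interval of the returned trace, s.
#' @return list with \code{trace} (canonical sensor-trace data.frame),
#'   \code{events} and the final \code{state}/\code{plant}.
#' @export
run_closed_loop <- function(cfg, tables, flock = NULL,
                            bldg = building_params(), weather,
                            duration_s = 3600, init = plant_state(),
                            record_every = 30) {
  if (is.null(flock)) {
    flock <- flock_params(N = cfg$flock$N, age = cfg$flock$age)
  }
  state <- init_controller_state(cfg)
  plant <- init
  times <- seq(0, duration_s, by = cfg$tick)
  rec_t <- seq(0, duration_s, by = record_every)
  rec <- vector("list", length(rec_t)); ri <- 1L
  events <- list()
  for (t in times) {
    wx <- weather(t)
    frame <- list(t = t, ti = plant$ti, to = wx$to, tih = plant$tih,
                  RH = plant$RH, RHout = wx$RHout, dp = plant$dp,
                  SAF = plant$SAF, NH3 = 0, CO2 = plant$CO2, CO = 0,
                  H2S = 0)
    r <- controller_step(state, frame, cfg, tables)
    state <- r$state
    if (length(r$events)) events <- c(events, r$events)
    if (ri <= length(rec_t) && t >= rec_t[ri]) {
      rec[[ri]] <- data.frame(t = t, ti = plant$ti, to = wx$to,
                              tih = plant$tih, RH = plant$RH,
                              RHout = wx$RHout, dp = plant$dp,
                              SAF = plant$SAF, NH3 = 0, CO2 = plant$CO2,
                              CO = 0, H2S = 0)
      ri <- ri + 1L
    }
    plant <- plant_step(plant, state$act, wx, flock, bldg, cfg$tick)
  }
  list(trace = do.call(rbind, rec[seq_len(ri - 1L)]),
       events = events_to_df(events), state = state, plant = plant)
}
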
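#' Controller configuration
#'
#' Builds a validated configuration for the ventilation controller. All
#' arguments have working defaults for a generic seven-position-blind house;
#' per-building values (blind map, fan powers, flock) should always be set
#' explicitly for a real installation.
#'
#' @param tick controller clock step, s. All timers are integer ticks.
#' @param n_positions number of discrete blind positions (0 = closed).
#' @param blinds list describing the blind-position lookup:
#'   \code{dt1_breaks} (ascending indoor-outdoor temperature-difference
#'   breakpoints, deg C), \code{weight_breaks} (ascending total-live-weight
#'   breakpoints, kg; empty for a single column), \code{positions}
#'   (matrix/vector, rows = dt1 intervals low to high, cols = weight
#'   intervals; must be nonincreasing down each column as dt1 grows), and
#'   \code{tr_offset} (extra opening steps in transitional mode).
#' @param fans list with \code{power_map} (ventilation fan power percent per
#'   blind position) and \code{tunnel_full_saf} (air speed in m/s produced
#'   by the tunnel fans at 100\% power).
#' @param timers list with \code{ts2} (cycle time, min; \code{NULL} selects
#'   the age schedule: 7 min up to 14 days, 5 min after), \code{ts3}
#'   (ventilation-on time per cycle, s), \code{ts4} (actuator settling
#'   time, s), \code{ts3_step}/\code{ts3_bounds} (humidity-driven per-cycle
#'   adjustment, s), \code{ts_drying} (evaporative-pad drying time, min) and
#'   \code{emergency_ts2} (emergency cycle time, min).
#' @param gas list of gas limits in ppm: \code{NH3_max}, \code{CO2_max},
#'   \code{CO_max}, \code{H2S_eps} (detection floor; any H2S above it is a
#'   violation) and \code{warn_fraction} (pre-warning fraction of a limit).
#' @param dp list with \code{band} (differential-pressure operating band,
#'   Pa), \code{gain} (proportional power correction, percent per Pa) and
#'   \code{max_iter} (correction steps per cycle before a fault alert).
#' @param evap list with \code{rhout_cutoff}: outdoor RH (percent) at or
#'   above which evaporative cooling is not engaged.
#' @param emergency list with \code{blind_mode} (one of \code{"max"},
#'   \code{"x_plus_2"}, \code{"fixed"}) and \code{blind_pos} (position used
#'   when \code{blind_mode = "fixed"}).
#' @param prep list with \code{tpmin}, \code{tpmax} (building-preparation
#'   thermostat band, deg C) and \code{purge_s} (initial airing time, s).
#' @param flock list with \code{N} (birds) and \code{age} (days).
#' @param saf_tolerance relative deviation of measured tunnel air speed from
#'   its setpoint beyond which fan power is corrected.
#' @param dt3_max stratification threshold, deg C: ceiling-to-floor
#'   temperature difference above which circulation fans run.
#' @param heater_gain modulated-heating gain, percent per deg C of deficit
#'   below the optimum temperature.
#' @return object of class \code{controller_config}.
#' @export
controller_config <- function(tick = 1, n_positions = 7,
                              blinds = list(), fans = list(),
                              timers = list(), gas = list(), dp = list(),
                              evap = list(), emergency = list(),
                              prep = list(), flock = list(),
                              saf_tolerance = 0.1, dt3_max = 3,
                              heater_gain = 20) {
  merge1 <- function(default, user) utils::modifyList(default, user)
  cfg <- structure(list(
    tick = tick, n_positions = n_positions,
    blinds = merge1(list(dt1_breaks = c(0, 5, 15), weight_breaks = 10000,
                         positions = cbind(c(4, 3, 2, 1), c(5, 4, 3, 2)),
                         tr_offset = 1), blinds),
    fans = merge1(list(power_map = c(15, 25, 35, 45, 55, 65, 75),
                       tunnel_full_saf = 3.0), fans),
    timers = merge1(list(ts2 = NULL, ts3 = 30, ts4 = 10, ts3_step = 5,
                         ts3_bounds = c(10, 60), ts_drying = 30,
                         emergency_ts2 = 3), timers),
    gas = merge1(list(NH3_max = 15, CO2_max = 3000, CO_max = 4.4,
                      H2S_eps = 0.1, warn_fraction = 0.8), gas),
    dp = merge1(list(band = c(17.5, 30), gain = 1.0, max_iter = 20), dp),
    evap = merge1(list(rhout_cutoff = 80), evap),
    emergency = merge1(list(blind_mode = "max", blind_pos = NA), emergency),
    prep = merge1(list(tpmin = 28, tpmax = 32, purge_s = 60), prep),
    flock = merge1(list(N = 20000, age = 14), flock),
    saf_tolerance = saf_tolerance, dt3_max = dt3_max,
    heater_gain = heater_gain), class = "controller_config")
  # normalise YAML-sourced list columns to numeric vectors/matrix
  b <- cfg$blinds
  b$dt1_breaks <- as.numeric(unlist(b$dt1_breaks))
  b$weight_breaks <- as.numeric(unlist(b$weight_breaks))
  b$positions <- matrix(as.numeric(unlist(b$positions)),
                        nrow = length(b$dt1_breaks) + 1)
  cfg$blinds <- b
  cfg$fans$power_map <- as.numeric(unlist(cfg$fans$power_map))
  cfg$timers$ts3_bounds <- as.numeric(unlist(cfg$timers$ts3_bounds))
  cfg$dp$band <- as.numeric(unlist(cfg$dp$band))
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  b <- cfg$blinds
  b$positions <- as.matrix(b$positions)
  if (length(b$positions) == 0) stop("blind position map must not be empty")
  if (nrow(b$positions) != length(b$dt1_breaks) + 1) {
    stop("blind map needs one row per dt1 interval (breaks + 1)")
  }
  if (ncol(b$positions) != max(1, length(b$weight_breaks) + 1) &&
      !(length(b$weight_breaks) == 0 && ncol(b$positions) == 1)) {
    stop("blind map needs one column per weight interval")
  }
  if (any(apply(b$positions, 2, function(x) any(diff(x) > 0)))) {
    stop("blind position must be nonincreasing as dt1 grows")
  }
  if (length(cfg$fans$power_map) < cfg$n_positions) {
    stop("power_map must cover every blind position")
  }
  tm <- cfg$timers
  if (!is.null(tm$ts2) && tm$ts2 * 60 < tm$ts3) {
    stop("cycle time ts2 must exceed ventilation-on time ts3")
  }
  if (tm$ts3 < tm$ts4) stop("ts3 must be at least the settling time ts4")
  if (tm$ts3 < tm$ts3_bounds[1] || tm$ts3 > tm$ts3_bounds[2]) {
    stop("ts3 must lie within ts3_bounds")
  }
  g <- cfg$gas
  if (any(c(g$NH3_max, g$CO2_max, g$CO_max) <= 0) || g$H2S_eps < 0) {
    stop("gas limits must be positive (H2S floor nonnegative)")
  }
  if (g$warn_fraction <= 0 || g$warn_fraction >= 1) {
    stop("warn_fraction must lie in (0, 1)")
  }
  if (cfg$dp$band[1] >= cfg$dp$band[2]) stop("dp band must be increasing")
  if (!cfg$emergency$blind_mode %in% c("max", "x_plus_2", "fixed")) {
    stop("emergency blind_mode must be max, x_plus_2 or fixed")
  }
  if (cfg$emergency$blind_mode == "fixed" && is.na(cfg$emergency$blind_pos)) {
    stop("fixed emergency blind mode needs blind_pos")
  }
  if (cfg$prep$tpmin >= cfg$prep$tpmax) stop("tpmin must be below tpmax")
  if (cfg$evap$rhout_cutoff <= 0 || cfg$evap$rhout_cutoff > 100) {
    stop("rhout_cutoff must lie in (0, 100]")
  }
  invisible(cfg)
}

#' Cycle time for a flock age
#'
#' Longer cycles in the brooding period save heating energy; an explicit
#' \code{timers$ts2} in the config overrides the age schedule.
#'
#' @param cfg a [controller_config()].
#' @param age flock age in days; defaults to the configured flock.
#' @return cycle time in seconds.
#' @export
cycle_time <- function(cfg, age = cfg$flock$age) {
  ts2 <- cfg$timers$ts2
  if (is.null(ts2)) ts2 <- if (age <= 14) 7 else 5
  ts2 * 60
}

#' Read a controller configuration from YAML
#'
#' Accepts either nested documents or flat dotted keys
#' (e.g. \code{gas.CO2_max: 3000}); user keys are merged over the package
#' defaults and the result is validated.
#'
#' @param path YAML file.
#' @return a [controller_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  # unflatten dotted keys
  flat <- names(raw)[grepl(".", names(raw), fixed = TRUE)]
  for (key in flat) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    node <- raw[[key]]
    for (p in rev(parts)) node <- stats::setNames(list(node), p)
    raw[[key]] <- NULL
    raw <- utils::modifyList(raw, node)
  }
  args <- list()
  top <- c("tick", "n_positions", "saf_tolerance", "dt3_max", "heater_gain")
  nested <- c("blinds", "fans", "timers", "gas", "dp", "evap", "emergency",
              "prep", "flock")
  for (k in intersect(top, names(raw))) args[[k]] <- raw[[k]]
  for (k in intersect(nested, names(raw))) args[[k]] <- raw[[k]]
  unknown <- setdiff(names(raw), c(top, nested))
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(controller_config, args)
}

#' Write a controller configuration to YAML
#'
#' @param cfg a [controller_config()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(cfg, path) {
  x <- unclass(cfg)
  x$blinds$positions <- as.vector(as.matrix(x$blinds$positions))
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @export
print.controller_config <- function(x, ...) {
  cat("<controller_config>\n")
  cat(sprintf("  flock        : %d birds, %g days\n", x$flock$N, x$flock$age))
  cat(sprintf("  cycle        : %g s (ts3 %g s, ts4 %g s); emergency %g min\n",
              cycle_time(x), x$timers$ts3, x$timers$ts4,
              x$timers$emergency_ts2))
  cat(sprintf("  blinds       : %d positions, TR offset +%d\n",
              x$n_positions, x$blinds$tr_offset))
  cat(sprintf("  dp band      : %g-%g Pa\n", x$dp$band[1], x$dp$band[2]))
  cat(sprintf("  gas limits   : NH3 %g, CO2 %g, CO %g ppm (warn at %g%%)\n",
              x$gas$NH3_max, x$gas$CO2_max, x$gas$CO_max,
              100 * x$gas$warn_fraction))
  invisible(x)
}
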
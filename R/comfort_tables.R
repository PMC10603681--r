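#' Comfort knowledge base for broiler felt-temperature control
#'
#' Bundles the age-banded temperature/humidity setpoint schedule, the
#' wind-chill correction grid for 7-week-old broilers, the relative-humidity
#' felt-temperature correction grid, an age-scaling curve for the wind-chill
#' correction, and the age-to-maximum-air-speed map. The three grids ship as
#' plain CSV files under \code{inst/extdata} and are the package defaults.
#'
#' @param setpoints data.frame with columns \code{age_min}, \code{age_max}
#'   (NA for the open-ended last band), \code{tmax}, \code{tmin},
#'   \code{rh_min}, \code{rh_max}. Bands must tile ages 1... without gaps.
#' @param wind_chill list with \code{ti_axis} (ascending, deg C),
#'   \code{saf_axis} (ascending, m/s) and \code{tcw} matrix
#'   (rows = \code{ti_axis}, cols = \code{saf_axis}; NA marks combinations
#'   the controller must not command).
#' @param rh_correction list with \code{ti_axis} (ascending, deg C),
#'   \code{drh_breaks} (upper edges of the half-open delta-RH bins, percent)
#'   and \code{tcrh} matrix (rows = \code{ti_axis}, cols = bins).
#' @param age_scale data.frame with columns \code{age}, \code{scale}:
#'   piecewise-linear dimensionless scaling of the wind-chill grid for young
#'   birds. Default ramps from 0.3 at day 1 to 1.0 at day 35 and is a
#'   documented stand-in (only the 7-week grid is published).
#' @param zmax_map data.frame with columns \code{age}, \code{z}:
#'   piecewise-linear maximum permissible air speed (m/s) by age. Default
#'   0.8 m/s up to day 7, rising linearly to 2.5 m/s at day 49.
#' @param dir directory holding \code{table1_setpoints.csv},
#'   \code{table2_windchill.csv} and \code{table3_rhcorrection.csv};
#'   defaults to the files packaged with broilervent.
#'
#' @return An object of class \code{comfort_tables}.
#' @export
#' @examples
#' ct <- comfort_tables()
#' setpoints(14, ct)
comfort_tables <- function(setpoints = NULL, wind_chill = NULL,
                           rh_correction = NULL, age_scale = NULL,
                           zmax_map = NULL, dir = NULL) {
  if (is.null(dir)) dir <- system.file("extdata", package = "broilervent")
  if (is.null(setpoints)) {
    setpoints <- utils::read.csv(file.path(dir, "table1_setpoints.csv"))
  }
  if (is.null(wind_chill)) {
    wind_chill <- read_windchill_grid(file.path(dir, "table2_windchill.csv"))
  }
  if (is.null(rh_correction)) {
    rh_correction <- read_rhcorrection_grid(
      file.path(dir, "table3_rhcorrection.csv"))
  }
  if (is.null(age_scale)) {
    age_scale <- data.frame(age = c(1, 35), scale = c(0.3, 1))
  }
  if (is.null(zmax_map)) {
    zmax_map <- data.frame(age = c(7, 49), z = c(0.8, 2.5))
  }
  ct <- structure(
    list(setpoint_schedule = setpoints, wind_chill = wind_chill,
         rh_correction = rh_correction, age_scale = age_scale,
         zmax_map = zmax_map),
    class = "comfort_tables")
  validate_comfort_tables(ct)
  ct
}

read_windchill_grid <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  saf_axis <- as.numeric(sub("^saf_", "", names(d)[-1]))
  o <- order(d$ti)
  list(ti_axis = d$ti[o], saf_axis = saf_axis,
       tcw = as.matrix(d[o, -1, drop = FALSE]))
}

read_rhcorrection_grid <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  o <- order(d$ti)
  list(ti_axis = d$ti[o], drh_breaks = c(5, 10, 15, 20, 25, Inf),
       tcrh = as.matrix(d[o, -1, drop = FALSE]))
}

validate_comfort_tables <- function(ct) {
  sp <- ct$setpoint_schedule
  need <- c("age_min", "age_max", "tmax", "tmin", "rh_min", "rh_max")
  if (!all(need %in% names(sp))) {
    stop("setpoint schedule missing columns: ",
         paste(setdiff(need, names(sp)), collapse = ", "))
  }
  sp <- sp[order(sp$age_min), ]
  if (sp$age_min[1] > 1) stop("setpoint schedule must start at age 1")
  hi <- sp$age_max[-nrow(sp)]
  if (any(is.na(hi)) || any(sp$age_min[-1] != hi + 1)) {
    stop("setpoint age bands must tile ages without gaps or overlap")
  }
  if (any(sp$tmin > sp$tmax)) stop("tmin must not exceed tmax")
  if (any(sp$rh_min > sp$rh_max | sp$rh_min <= 0 | sp$rh_max > 100)) {
    stop("RH band must satisfy 0 < rh_min <= rh_max <= 100")
  }
  wc <- ct$wind_chill
  if (any(diff(wc$ti_axis) <= 0) || any(diff(wc$saf_axis) <= 0)) {
    stop("wind-chill grid axes must be strictly increasing")
  }
  if (any(wc$tcw < 0, na.rm = TRUE)) stop("tcw must be nonnegative")
  # each row's defined cells form a prefix of the SAF axis and are monotone
  for (i in seq_along(wc$ti_axis)) {
    row <- wc$tcw[i, ]
    def <- !is.na(row)
    if (any(diff(def) > 0)) {
      stop("undefined wind-chill cells must be contiguous at high SAF")
    }
    if (any(diff(row[def]) < 0)) {
      stop("tcw must be nondecreasing in SAF at fixed ti")
    }
  }
  if (any(wc$tcw[, 1] != 0)) stop("tcw at 0.5 m/s must be zero")
  rc <- ct$rh_correction
  if (any(rc$tcrh < 0)) stop("tcRH must be nonnegative")
  if (any(t(apply(rc$tcrh, 1, diff)) < 0)) {
    stop("tcRH must be nondecreasing across delta-RH bins at fixed ti")
  }
  as <- ct$age_scale
  if (any(as$scale <= 0 | as$scale > 1)) stop("age_scale must lie in (0, 1]")
  zm <- ct$zmax_map
  if (any(diff(zm$z) < 0)) stop("zmax_map must be nondecreasing in age")
  invisible(ct)
}

#' @export
print.comfort_tables <- function(x, ...) {
  wc <- x$wind_chill
  cat("<comfort_tables>\n")
  cat(sprintf("  setpoint bands : %d (ages %d+)\n",
              nrow(x$setpoint_schedule), min(x$setpoint_schedule$age_min)))
  cat(sprintf("  wind chill     : %d x %d grid, ti %g..%g degC, SAF %g..%g m/s\n",
              length(wc$ti_axis), length(wc$saf_axis),
              min(wc$ti_axis), max(wc$ti_axis),
              min(wc$saf_axis), max(wc$saf_axis)))
  cat(sprintf("  RH correction  : %d x %d grid\n",
              length(x$rh_correction$ti_axis), ncol(x$rh_correction$tcrh)))
  invisible(x)
}
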
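#' Age-dependent comfort setpoints
#'
#' Looks up the temperature and relative-humidity comfort band for a flock
#' age. The optimum temperature is the midpoint of the band; the open-ended
#' last band applies to all older birds.
#'
#' @param ts1 broiler age in days (>= 1).
#' @param tables a [comfort_tables()] object.
#' @return list of class \code{setpoints} with \code{tmin}, \code{tmax},
#'   \code{topt} (deg C) and \code{rh_min}, \code{rh_max} (percent).
#' @export
#' @examples
#' setpoints(14, comfort_tables())  # tmin 24, tmax 27, topt 25.5
setpoints <- function(ts1, tables) {
  if (ts1 < 1) stop("broiler age must be >= 1 day")
  sp <- tables$setpoint_schedule
  i <- which(sp$age_min <= ts1 & (is.na(sp$age_max) | ts1 <= sp$age_max))
  if (length(i) == 0) i <- nrow(sp)
  i <- i[1]
  structure(list(tmin = sp$tmin[i], tmax = sp$tmax[i],
                 topt = (sp$tmin[i] + sp$tmax[i]) / 2,
                 rh_min = sp$rh_min[i], rh_max = sp$rh_max[i]),
            class = "setpoints")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Wind-chill correction to the felt temperature
#'
#' Bilinear interpolation on the 7-week wind-chill grid, scaled down for
#' younger birds by the age-scale curve. Air speeds at or below 0.5 m/s and
#' air temperatures at or above the top of the grid produce no chill.
#' Inputs outside the grid hull are clamped to it. Where the grid marks a
#' (ti, SAF) combination as undefined (a speed the controller must not
#' command at that temperature), the lookup clamps to the nearest defined
#' speed column and flags the result via the \code{"x_clamped"} attribute.
#'
#' @param ti indoor air temperature, deg C.
#' @param SAF speed of air flow over the birds, m/s (>= 0).
#' @param ts1 broiler age in days.
#' @param tables a [comfort_tables()] object.
#' @return tcw in deg C (vectorised over \code{ti}/\code{SAF}), with a
#'   logical attribute \code{x_clamped}.
#' @export
#' @examples
#' wind_chill(30, 2.5, 49, comfort_tables())  # 5.8
wind_chill <- function(ti, SAF, ts1, tables) {
  if (any(SAF < 0)) stop("SAF must be nonnegative")
  n <- max(length(ti), length(SAF))
  ti <- rep_len(ti, n); SAF <- rep_len(SAF, n)
  out <- numeric(n); flag <- logical(n)
  for (k in seq_len(n)) {
    r <- wind_chill_scalar(ti[k], SAF[k], tables$wind_chill)
    out[k] <- r$tcw; flag[k] <- r$x_clamped
  }
  out <- out * age_scale_factor(ts1, tables)
  attr(out, "x_clamped") <- flag
  out
}

wind_chill_scalar <- function(ti, saf, wc) {
  if (saf <= 0.5 || ti >= max(wc$ti_axis)) {
    return(list(tcw = 0, x_clamped = FALSE))
  }
  ti_c <- clamp(ti, min(wc$ti_axis), max(wc$ti_axis))
  saf_c <- clamp(saf, min(wc$saf_axis), max(wc$saf_axis))
  i <- findInterval(ti_c, wc$ti_axis)
  i2 <- min(i + 1, length(wc$ti_axis))
  w <- if (i2 == i) 0 else
    (ti_c - wc$ti_axis[i]) / (wc$ti_axis[i2] - wc$ti_axis[i])
  flag <- FALSE
  row_val <- function(r) {
    row <- wc$tcw[r, ]
    def <- which(!is.na(row))
    s_max <- wc$saf_axis[max(def)]
    s <- saf_c
    if (s > s_max) { s <- s_max; flag <<- TRUE }
    stats::approx(wc$saf_axis[def], row[def], xout = s)$y
  }
  v <- (1 - w) * row_val(i) + w * row_val(i2)
  list(tcw = v, x_clamped = flag)
}

age_scale_factor <- function(ts1, tables) {
  as <- tables$age_scale
  stats::approx(as$age, as$scale, xout = ts1, rule = 2)$y
}

#' Relative-humidity correction to the felt temperature
#'
#' When indoor RH exceeds the upper bound of the age band's humidity range
#' by more than 1 percentage point, the felt temperature rises by the grid
#' value for the matching delta-RH bin, linearly interpolated in temperature
#' between the grid's 1-degree rows. Temperatures are clamped to the grid
#' range; excesses beyond the last bin use the last bin.
#'
#' @param ti indoor air temperature, deg C.
#' @param RH indoor relative humidity, percent (0..100).
#' @param ts1 broiler age in days.
#' @param tables a [comfort_tables()] object.
#' @return tcRH in deg C (vectorised over \code{ti}/\code{RH}).
#' @export
#' @examples
#' ct <- comfort_tables()
#' rh_correction(25, setpoints(49, ct)$rh_max + 22, 49, ct)  # 1.5
rh_correction <- function(ti, RH, ts1, tables) {
  if (any(RH < 0 | RH > 100)) stop("RH must lie in [0, 100]")
  rhmax <- setpoints(ts1, tables)$rh_max
  rc <- tables$rh_correction
  n <- max(length(ti), length(RH))
  ti <- rep_len(ti, n); RH <- rep_len(RH, n)
  out <- numeric(n)
  for (k in seq_len(n)) {
    drh <- RH[k] - rhmax
    if (drh <= 1) next
    bin <- sum(drh > rc$drh_breaks[-length(rc$drh_breaks)]) + 1
    ti_c <- clamp(ti[k], min(rc$ti_axis), max(rc$ti_axis))
    out[k] <- stats::approx(rc$ti_axis, rc$tcrh[, bin], xout = ti_c)$y
  }
  out
}

#' Felt temperature of the flock
#'
#' The temperature the birds effectively experience:
#' \code{tf = ti - tcw + tcRH}, combining the wind-chill cooling of moving
#' air with the reduced evaporative cooling under excess humidity. When the
#' air is still (SAF <= 0.5 m/s) and RH is within the comfort band, the felt
#' temperature equals the measured temperature.
#'
#' @inheritParams wind_chill
#' @param RH indoor relative humidity, percent.
#' @return tf in deg C.
#' @export
#' @examples
#' felt_temperature(30, 2.5, 60, 49, comfort_tables())  # 24.2
felt_temperature <- function(ti, SAF, RH, ts1, tables) {
  tcw <- wind_chill(ti, SAF, ts1, tables)
  tf <- ti - as.numeric(tcw) + rh_correction(ti, RH, ts1, tables)
  attr(tf, "x_clamped") <- attr(tcw, "x_clamped")
  tf
}

#' Maximum permissible tunnel air speed for a flock age
#'
#' Young birds tolerate only gentle air movement (about 0.8-1 m/s); adults
#' up to 2.5-3 m/s. The default map rises linearly between those published
#' anchors and can be replaced wholesale in [comfort_tables()].
#'
#' @inheritParams setpoints
#' @return Zmax in m/s.
#' @export
max_airspeed <- function(ts1, tables) {
  if (ts1 < 1) stop("broiler age must be >= 1 day")
  zm <- tables$zmax_map
  stats::approx(zm$age, zm$z, xout = ts1, rule = 2)$y
}

#' Air speed achieving the optimal felt temperature
#'
#' Scans candidate tunnel air speeds from 0.5 m/s up to the age's maximum on
#' a fixed-resolution grid and returns the smallest speed whose felt
#' temperature does not exceed the optimum. If even the maximum speed cannot
#' cool the flock to the optimum, the maximum is returned with
#' \code{saturated = TRUE}.
#'
#' @inheritParams felt_temperature
#' @param step search-grid resolution in m/s; finer than any real fan
#'   actuator resolves.
#' @return list with \code{z} (m/s), \code{saturated} (logical) and
#'   \code{tf} (felt temperature at \code{z}).
#' @export
optimal_airspeed <- function(ti, RH, ts1, tables, step = 0.05) {
  zmax <- max_airspeed(ts1, tables)
  topt <- setpoints(ts1, tables)$topt
  grid <- unique(c(seq(0.5, zmax, by = step), zmax))
  for (z in grid) {
    tf <- as.numeric(felt_temperature(ti, z, RH, ts1, tables))
    if (tf <= topt) {
      return(list(z = z, saturated = FALSE, tf = tf))
    }
  }
  list(z = zmax, saturated = TRUE,
       tf = as.numeric(felt_temperature(ti, zmax, RH, ts1, tables)))
}

#' @export
print.setpoints <- function(x, ...) {
  cat(sprintf("<setpoints> tmin %.1f, topt %.2f, tmax %.1f degC; RH %g-%g%%\n",
              x$tmin, x$topt, x$tmax, x$rh_min, x$rh_max))
  invisible(x)
}
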
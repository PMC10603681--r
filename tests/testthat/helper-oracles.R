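# Independent brute-force oracles, deliberately coded differently from the
# package implementation.

# plain corner-weight bilinear interpolation on the wind-chill grid; only
# valid where all four surrounding cells are defined
bilinear_oracle <- function(ti, saf, wc) {
  ia <- max(which(wc$ti_axis <= ti)); ib <- min(ia + 1, length(wc$ti_axis))
  ja <- max(which(wc$saf_axis <= saf)); jb <- min(ja + 1, length(wc$saf_axis))
  u <- if (ib == ia) 0 else (ti - wc$ti_axis[ia]) /
    (wc$ti_axis[ib] - wc$ti_axis[ia])
  v <- if (jb == ja) 0 else (saf - wc$saf_axis[ja]) /
    (wc$saf_axis[jb] - wc$saf_axis[ja])
  q <- wc$tcw[c(ia, ib), c(ja, jb), drop = FALSE]
  stopifnot(!anyNA(q))
  (1 - u) * (1 - v) * q[1, 1] + (1 - u) * v * q[1, 2] +
    u * (1 - v) * q[2, 1] + u * v * q[2, 2]
}

# row-interpolation oracle for the humidity-correction grid
rh_oracle <- function(ti, drh, rc) {
  bins <- c(5, 10, 15, 20, 25)
  b <- sum(drh > bins) + 1
  ia <- max(which(rc$ti_axis <= ti)); ib <- min(ia + 1, length(rc$ti_axis))
  u <- if (ib == ia) 0 else (ti - rc$ti_axis[ia]) /
    (rc$ti_axis[ib] - rc$ti_axis[ia])
  (1 - u) * rc$tcrh[ia, b] + u * rc$tcrh[ib, b]
}

# exhaustive scan for the smallest air speed reaching the optimum felt
# temperature (vectorised, independent of the package loop)
zopt_oracle <- function(ti, RH, ts1, tables, step = 0.05) {
  zmax <- max_airspeed(ts1, tables)
  topt <- setpoints(ts1, tables)$topt
  grid <- unique(c(seq(0.5, zmax, by = step), zmax))
  tf <- vapply(grid, function(z)
    as.numeric(felt_temperature(ti, z, RH, ts1, tables)), numeric(1))
  hit <- which(tf <= topt)
  if (length(hit) == 0) list(z = zmax, saturated = TRUE)
  else list(z = grid[min(hit)], saturated = FALSE)
}
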
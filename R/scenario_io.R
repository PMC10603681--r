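trace_required_cols <- c("t", "ti", "to", "tih", "RH", "RHout", "dp", "SAF")
trace_gas_cols <- c("NH3", "CO2", "CO", "H2S")

#' Read a sensor trace CSV
#'
#' Canonical dialect: comma-separated, header row, '.' decimal, UTF-8,
#' time in seconds, strictly increasing. Missing gas columns default to 0
#' with a warning; malformed rows are reported with their line number.
#'
#' @param path CSV file.
#' @return validated data.frame with columns \code{t, ti, to, tih, RH,
#'   RHout, dp, SAF, NH3, CO2, CO, H2S}.
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  d <- utils::read.csv(path, strip.white = TRUE)
  if (nrow(d) == 0) stop("trace file is empty: ", path)
  missing_req <- setdiff(trace_required_cols, names(d))
  if (length(missing_req)) {
    stop("trace missing required columns: ",
         paste(missing_req, collapse = ", "))
  }
  for (g in setdiff(trace_gas_cols, names(d))) {
    warning("trace has no ", g, " column; assuming 0 ppm")
    d[[g]] <- 0
  }
  d <- d[, c(trace_required_cols, trace_gas_cols)]
  for (cn in names(d)) {
    d[[cn]] <- suppressWarnings(as.numeric(d[[cn]]))
    bad <- which(is.na(d[[cn]]))
    if (length(bad)) {
      stop(sprintf("malformed value in column %s at line %d of %s", cn,
                   bad[1] + 1L, path))
    }
  }
  if (any(diff(d$t) <= 0)) {
    stop("trace times must be strictly increasing (line ",
         which(diff(d$t) <= 0)[1] + 2L, ")")
  }
  if (any(d$RH < 0 | d$RH > 100 | d$RHout < 0 | d$RHout > 100)) {
    stop("RH values must lie in [0, 100]")
  }
  if (any(d[trace_gas_cols] < 0)) stop("gas readings must be nonnegative")
  d
}

#' Write a sensor trace CSV in the canonical dialect
#'
#' @param trace data.frame as returned by [read_trace()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an event log as JSON lines
#'
#' One JSON object per line: \code{{"t": ..., "kind": "actuator|alert|mode",
#' "name": ..., "value": ...}}.
#'
#' @param events data.frame from [replay_trace()] or [run_closed_loop()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_events <- function(events, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(events))) {
    writeLines(jsonlite::toJSON(list(t = events$t[i], kind = events$kind[i],
                                     name = events$name[i],
                                     value = events$value[i]),
                                auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' Read a JSON-lines event log
#'
#' @param path file written by [write_events()].
#' @return data.frame with columns \code{t}, \code{kind}, \code{name},
#'   \code{value}.
#' @export
read_events <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- lapply(lines, jsonlite::fromJSON)
  data.frame(t = vapply(recs, function(r) as.numeric(r$t), numeric(1)),
             kind = vapply(recs, function(r) r$kind, character(1)),
             name = vapply(recs, function(r) r$name, character(1)),
             value = vapply(recs, function(r) as.character(r$value),
                            character(1)),
             stringsAsFactors = FALSE)
}

#' Read an expectations table
#'
#' CSV with columns \code{t_start}, \code{t_end} (s), \code{kind},
#' \code{name} and \code{match} (a regular expression applied to the event
#' value; empty matches any value).
#'
#' @param path CSV file.
#' @return data.frame of expectations.
#' @export
read_expectations <- function(path) {
  d <- utils::read.csv(path, strip.white = TRUE,
                       colClasses = c(match = "character"))
  need <- c("t_start", "t_end", "kind", "name", "match")
  if (!all(need %in% names(d))) {
    stop("expectations file needs columns: ", paste(need, collapse = ", "))
  }
  if (any(d$t_start < 0 | d$t_end < d$t_start)) {
    stop("expectation windows must be nonnegative and ordered")
  }
  d
}

#' Compare an event log against expectations
#'
#' Each expectation passes when at least one logged event of the given kind
#' and name falls inside its time window with a value matching the regular
#' expression. An expectation whose window lies beyond the end of the log
#' fails with reason \code{"window beyond trace"}.
#'
#' @param actual event-log data.frame.
#' @param expected expectations data.frame (see [read_expectations()]).
#' @return data.frame of per-expectation results (\code{pass},
#'   \code{n_matched}, \code{detail}) with attribute \code{ok} (overall
#'   logical); class \code{event_comparison}.
#' @export
compare_events <- function(actual, expected) {
  t_max <- if (nrow(actual)) max(actual$t) else -Inf
  res <- expected
  res$pass <- logical(nrow(expected))
  res$n_matched <- integer(nrow(expected))
  res$detail <- character(nrow(expected))
  for (i in seq_len(nrow(expected))) {
    e <- expected[i, ]
    if (e$t_start > t_max) {
      res$detail[i] <- "window beyond trace"
      next
    }
    sel <- actual$t >= e$t_start & actual$t <= e$t_end &
      actual$kind == e$kind & actual$name == e$name
    if (nzchar(e$match)) sel <- sel & grepl(e$match, actual$value)
    res$n_matched[i] <- sum(sel)
    res$pass[i] <- any(sel)
    if (!res$pass[i]) {
      near <- actual[actual$t >= e$t_start & actual$t <= e$t_end &
                       actual$name == e$name, ]
      res$detail[i] <- if (nrow(near))
        sprintf("no match; nearest value(s): %s",
                paste(utils::head(near$value, 3), collapse = ", "))
      else "no event of this name in window"
    }
  }
  structure(res, ok = all(res$pass), class = c("event_comparison",
                                               "data.frame"))
}

#' @export
print.event_comparison <- function(x, ...) {
  ok <- attr(x, "ok")
  cat(sprintf("Event comparison: %d/%d expectations met%s\n",
              sum(x$pass), nrow(x), if (ok) "" else " [FAIL]"))
  bad <- x[!x$pass, , drop = FALSE]
  for (i in seq_len(nrow(bad))) {
    cat(sprintf("  FAIL [%g,%g] %s/%s ~ '%s': %s\n", bad$t_start[i],
                bad$t_end[i], bad$kind[i], bad$name[i], bad$match[i],
                bad$detail[i]))
  }
  invisible(x)
}

#' Packaged reference artefacts
#'
#' Paths to the packaged reference replay fixtures: the simulated sensor
#' trace, the matching controller configuration, and the expectations
#' encoding the published minute-by-minute behaviour.
#'
#' @param which one of \code{"trace"}, \code{"config"},
#'   \code{"expectations"}.
#' @return file path.
#' @export
reference_fixture <- function(which = c("trace", "config", "expectations")) {
  which <- match.arg(which)
  f <- switch(which, trace = "table5_trace.csv",
              config = "table5_config.yaml",
              expectations = "table5_expected.csv")
  system.file("extdata", f, package = "broilervent", mustWork = TRUE)
}

#' Generate a deterministic test scenario trace
#'
#' \code{"table5"} reproduces the packaged reference trace exactly (the
#' seed is ignored). The other kinds synthesise weather-driven sensor
#' traces with seeded autoregressive noise: \code{"cold_day"} (winter day,
#' minimum-ventilation territory), \code{"hot_day"} (summer heat pushing
#' into tunnel and evaporative cooling) and \code{"gas_spike"} (a CO2
#' excursion over the limit and back). Same kind and seed give identical
#' traces.
#'
#' @param kind scenario name.
#' @param seed integer seed.
#' @param duration_s trace length, s.
#' @param by row spacing, s.
#' @return canonical trace data.frame.
#' @export
make_scenario <- function(kind = c("table5", "cold_day", "hot_day",
                                   "gas_spike"),
                          seed = 1, duration_s = 7200, by = 30) {
  kind <- match.arg(kind)
  if (kind == "table5") return(read_trace(reference_fixture("trace")))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  t <- seq(0, duration_s, by = by)
  n <- length(t)
  ar_noise <- function(sd) {
    e <- stats::rnorm(n, 0, sd)
    as.numeric(stats::filter(e, 0.9, method = "recursive"))
  }
  day <- sin(2 * pi * t / 86400)
  base <- switch(kind,
    cold_day = list(to = 2 + 4 * day, rhout = 80, ti0 = 23, co2 = 900),
    hot_day = list(to = 28 + 6 * day, rhout = 55, ti0 = 29, co2 = 700),
    gas_spike = list(to = 10 + 4 * day, rhout = 70, ti0 = 25, co2 = 800))
  to <- base$to + ar_noise(0.2)
  ti <- base$ti0 + 0.15 * (to - mean(to)) + ar_noise(0.1)
  co2 <- pmax(base$co2 + ar_noise(20), 420)
  if (kind == "gas_spike") {
    mid <- duration_s / 2
    co2 <- co2 + 2800 * exp(-((t - mid) / (duration_s / 12))^2)
  }
  data.frame(t = t, ti = round(ti, 2), to = round(to, 2),
             tih = round(ti + 2.5, 2),
             RH = round(clamp(68 + ar_noise(0.5), 1, 100), 1),
             RHout = round(clamp(base$rhout + ar_noise(1), 1, 100), 1),
             dp = round(clamp(22 + ar_noise(0.8), 0, 60), 1),
             SAF = 0.25, NH3 = 0, CO2 = round(co2), CO = 0, H2S = 0)
}
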
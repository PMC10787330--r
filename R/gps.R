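# GPS-defined work hours: 1-km geofence around registered workplaces with a
# 1800-s dwell confirmation for both the start and the stop trigger.

#' Haversine distance
#'
#' Great-circle distance on a sphere of radius 6371 km. Vectorised over
#' rows; `a` and `b` recycle to a common length.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in degrees.
#' @return Distance in km.
#' @examples
#' haversine_km(0, 0, 0, 1) # ~111.19 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

seconds_of_day <- function(ts, tz) {
  lt <- as.POSIXlt(ts, tz = tz)
  lt$hour * 3600 + lt$min * 60 + lt$sec
}

local_date <- function(ts, tz) as.Date(ts, tz = tz)

#' Label GPS-defined work intervals
#'
#' Implements the work-hour state machine: recording starts when the device
#' has been continuously within `geofence_radius_km` of any registered
#' workplace for `confirm_s` seconds, and stops when it has been
#' continuously out of range for `confirm_s` seconds. The confirmation is a
#' latency only: the interval is backdated to the first in-range fix of the
#' qualifying run and ends at the last in-range fix before the qualifying
#' out-of-range run. A gap without fixes longer than `confirm_s` counts as
#' out of range. Intervals spanning midnight are split at local midnight.
#'
#' @param gps GPS tibble (`participant_id, timestamp, lat, lon`), time
#'   sorted within participant.
#' @param workplaces Tibble or data frame with columns `lat`, `lon`
#'   (1 to 5 rows).
#' @param cfg A [pipeline_config()].
#' @return Tibble `participant_id, date, start, end` of disjoint, sorted
#'   work intervals.
#' @export
label_work_intervals <- function(gps, workplaces, cfg = pipeline_config()) {
  if (is.null(workplaces) || nrow(workplaces) == 0) {
    abort("at least one workplace is required")
  }
  if (nrow(workplaces) > 5) abort("at most 5 workplaces can be registered")
  if (nrow(gps) == 0) {
    return(tibble(participant_id = character(), date = as.Date(character()),
                  start = as.POSIXct(character(), tz = cfg$tz),
                  end = as.POSIXct(character(), tz = cfg$tz)))
  }
  gps |>
    group_by(.data$participant_id) |>
    dplyr::group_modify(function(g, key) {
      scan_track(g, workplaces, cfg)
    }) |>
    ungroup() |>
    select("participant_id", "date", "start", "end")
}

scan_track <- function(g, workplaces, cfg) {
  g <- g[order(g$timestamp), ]
  d <- rep(Inf, nrow(g))
  for (w in seq_len(nrow(workplaces))) {
    d <- pmin(d, haversine_km(g$lat, g$lon, workplaces$lat[w], workplaces$lon[w]))
  }
  inr <- d <= cfg$geofence_radius_km
  tt <- as.numeric(g$timestamp)

  # runs of constant in/out state, split additionally at gaps > confirm_s
  gap <- c(FALSE, diff(tt) > cfg$confirm_s)
  run_id <- cumsum(c(TRUE, inr[-1] != inr[-length(inr)]) | gap)
  first_i <- which(!duplicated(run_id))
  last_i <- c(first_i[-1] - 1L, length(run_id))
  r_in <- inr[first_i]
  r_t0 <- tt[first_i]; r_t1 <- tt[last_i]
  gap_before <- c(Inf, r_t0[-1] - r_t1[-length(r_t1)])

  on <- FALSE; start <- NA_real_; last_in <- NA_real_
  out <- list()
  for (k in seq_along(r_in)) {
    if (on && k > 1 && gap_before[k] > cfg$confirm_s) {
      out[[length(out) + 1L]] <- c(start, last_in)
      on <- FALSE
    }
    span <- r_t1[k] - r_t0[k]
    if (r_in[k]) {
      if (!on && span >= cfg$confirm_s) {
        on <- TRUE; start <- r_t0[k]
      }
      if (on) last_in <- r_t1[k]
    } else if (on && span >= cfg$confirm_s) {
      out[[length(out) + 1L]] <- c(start, last_in)
      on <- FALSE
    }
  }
  if (on) out[[length(out) + 1L]] <- c(start, last_in)
  if (!length(out)) {
    return(tibble(date = as.Date(character()),
                  start = as.POSIXct(character(), tz = cfg$tz),
                  end = as.POSIXct(character(), tz = cfg$tz)))
  }
  m <- do.call(rbind, out)
  iv <- tibble(start = as.POSIXct(m[, 1], tz = cfg$tz, origin = "1970-01-01"),
               end = as.POSIXct(m[, 2], tz = cfg$tz, origin = "1970-01-01"))
  iv <- iv[as.numeric(iv$end) > as.numeric(iv$start), ]
  split_at_midnight(iv, cfg$tz)
}

split_at_midnight <- function(iv, tz) {
  pieces <- pmap(iv, function(start, end) {
    d0 <- local_date(start, tz); d1 <- local_date(end, tz)
    days <- seq(d0, d1, by = "day")
    mids <- as.POSIXct(paste(days, "00:00:00"), tz = tz)
    s <- pmax(as.numeric(start), as.numeric(mids))
    e <- pmin(as.numeric(end), as.numeric(mids) + 86400)
    tibble(date = days,
           start = as.POSIXct(s, tz = tz, origin = "1970-01-01"),
           end = as.POSIXct(e, tz = tz, origin = "1970-01-01"))
  })
  out <- list_rbind(pieces)
  out[as.numeric(out$end) > as.numeric(out$start), ]
}

#' Rasterise work intervals to a per-minute indicator
#'
#' For each requested day, marks minute `m` (minute of local day) as
#' at-work iff the half-open minute `[m, m+1)` intersects any work
#' interval. The evaluated span is 05:45-24:00, 1095 minutes.
#'
#' @param intervals Interval tibble from [label_work_intervals()].
#' @param dates Days to rasterise (defaults to the interval dates).
#' @param participant_id Participant the grid belongs to (required when
#'   `intervals` is empty).
#' @param cfg A [pipeline_config()].
#' @return Tibble `participant_id, date, minute, at_work` (0/1).
#' @export
minute_gps_state <- function(intervals, dates = NULL, participant_id = NULL,
                             cfg = pipeline_config()) {
  if (is.null(dates)) dates <- sort(unique(intervals$date))
  if (is.null(participant_id)) {
    participant_id <- if (nrow(intervals)) intervals$participant_id[1] else NA_character_
  }
  grids <- map(dates, function(d) {
    iv <- intervals[intervals$date == d, ]
    at <- rep(0L, length(.GRID_MIN))
    if (nrow(iv)) {
      s <- seconds_of_day(iv$start, cfg$tz)
      e <- seconds_of_day(iv$end, cfg$tz)
      e[e == 0] <- 86400  # interval ending exactly at midnight
      for (i in seq_along(s)) {
        at <- pmax(at, as.integer(.GRID_MIN * 60 < e[i] & (.GRID_MIN + 1) * 60 > s[i]))
      }
    }
    tibble(participant_id = participant_id, date = d,
           minute = .GRID_MIN, at_work = at)
  })
  list_rbind(grids)
}

#' Classify a person-day
#'
#' A day with no work interval is a `holiday` (zero GPS-defined work
#' hours). A `typical` workday is off-working at both ends of the evaluated
#' span (05:45 and 23:59), starts working before noon and accumulates more
#' than four hours of work (sum of interval durations). Anything else is
#' `other`.
#'
#' @param intervals Work intervals of the single day.
#' @param minute_state The day's per-minute indicator from
#'   [minute_gps_state()].
#' @param cfg A [pipeline_config()].
#' @return One of `"typical"`, `"holiday"`, `"other"`.
#' @export
classify_day <- function(intervals, minute_state, cfg = pipeline_config()) {
  if (nrow(intervals) == 0) return("holiday")
  at <- minute_state$at_work[order(minute_state$minute)]
  first_off <- at[1] == 0L
  last_off <- at[length(at)] == 0L
  start_min <- min(seconds_of_day(intervals$start, cfg$tz)) / 60
  total_h <- sum(as.numeric(intervals$end) - as.numeric(intervals$start)) / 3600
  if (first_off && last_off && start_min < 720 && total_h > 4) "typical" else "other"
}

#' Classify all person-days of a track
#'
#' @param intervals Interval tibble (may span participants).
#' @param minute_states Output of [minute_gps_state()] covering all days.
#' @param cfg A [pipeline_config()].
#' @return Tibble `participant_id, date, day_class, work_h`.
#' @export
classify_days <- function(intervals, minute_states, cfg = pipeline_config()) {
  minute_states |>
    distinct(.data$participant_id, .data$date) |>
    pmap(function(participant_id, date) {
      iv <- intervals[intervals$participant_id == participant_id &
                        intervals$date == date, ]
      ms <- minute_states[minute_states$participant_id == participant_id &
                            minute_states$date == date, ]
      tibble(
        participant_id = participant_id, date = date,
        day_class = classify_day(iv, ms, cfg),
        work_h = sum(as.numeric(iv$end) - as.numeric(iv$start)) / 3600
      )
    }) |>
    list_rbind()
}
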
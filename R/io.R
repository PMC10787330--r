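# On-disk formats: plain CSV, ISO-8601 timestamps with explicit UTC offsets.
# All computation downstream happens in the participant's local time zone.

.EVENT_KINDS <- c("screen_on", "screen_off", "notification")
.KIND_PRIORITY <- c(notification = 0L, screen_off = 1L, screen_on = 2L)

format_ts <- function(x) format(x, "%Y-%m-%dT%H:%M:%S%z")

parse_ts <- function(x, tz, path) {
  ts <- suppressWarnings(lubridate::ymd_hms(x, tz = "UTC", quiet = TRUE))
  bad <- which(is.na(ts) | is.na(x))
  if (length(bad)) {
    abort(sprintf("%s: malformed timestamp %s at line %d",
                  path, shQuote(x[bad[1]]), bad[1] + 1L))
  }
  lubridate::with_tz(ts, tz)
}

read_csv_quiet <- function(path, col_types) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  readr::read_csv(path, col_types = col_types, progress = FALSE)
}

#' Read an event log
#'
#' Events are stored one per row as
#' `participant_id,timestamp,kind,app_label` with ISO-8601 timestamps
#' carrying an explicit UTC offset. `kind` is one of `screen_on`,
#' `screen_off`, `notification`. The app label names the active app for
#' `screen_on`, the posting app for `notification`, and may be empty for
#' `screen_off`. Records are returned sorted by participant and timestamp
#' (with `screen_off` before `screen_on` on ties so that zero-gap app
#' switches stay well formed).
#'
#' @param path CSV file path.
#' @param tz Local time zone in which downstream wall-clock rules apply.
#' @return A tibble `participant_id, timestamp, kind, app_label`.
#' @export
read_events <- function(path, tz = "Asia/Taipei") {
  x <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), timestamp = readr::col_character(),
    kind = readr::col_character(), app_label = readr::col_character()
  ))
  bad <- which(!(x$kind %in% .EVENT_KINDS))
  if (length(bad)) {
    abort(sprintf("%s: unknown event kind %s at line %d",
                  path, shQuote(x$kind[bad[1]]), bad[1] + 1L))
  }
  x$timestamp <- parse_ts(x$timestamp, tz, path)
  x$app_label[is.na(x$app_label)] <- ""
  x[order(x$participant_id, x$timestamp, .KIND_PRIORITY[x$kind]), ] |> as_tibble()
}

#' Write an event log
#' @param events Tibble as returned by [read_events()] or [simulate_days()].
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  out <- events
  out$timestamp <- format_ts(out$timestamp)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a GPS log
#'
#' Fixes are stored as `participant_id,timestamp,lat,lon`; the nominal
#' cadence is one fix per 600 seconds but gaps are allowed. Coordinates are
#' validated against their ranges.
#'
#' @inheritParams read_events
#' @return A tibble `participant_id, timestamp, lat, lon`, sorted.
#' @export
read_gps <- function(path, tz = "Asia/Taipei") {
  x <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), timestamp = readr::col_character(),
    lat = readr::col_double(), lon = readr::col_double()
  ))
  bad <- which(is.na(x$lat) | is.na(x$lon) | abs(x$lat) > 90 | abs(x$lon) > 180)
  if (length(bad)) {
    abort(sprintf("%s: coordinate out of range (lat %s, lon %s) at line %d",
                  path, format(x$lat[bad[1]]), format(x$lon[bad[1]]), bad[1] + 1L))
  }
  x$timestamp <- parse_ts(x$timestamp, tz, path)
  x[order(x$participant_id, x$timestamp), ] |> as_tibble()
}

#' Write a GPS log
#' @inheritParams write_events
#' @param gps Tibble `participant_id, timestamp, lat, lon`.
#' @export
write_gps <- function(gps, path) {
  out <- gps
  out$timestamp <- format_ts(out$timestamp)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Write / read a probability series
#'
#' Per-minute work-mode probabilities are stored as
#' `participant_id,date,minute,provisional,final`; minutes are minute of the
#' local day (05:45 is 345) and must be contiguous within each day.
#'
#' @param series Tibble `participant_id, date, minute, provisional, final`.
#' @param path Destination CSV path.
#' @return `path` invisibly; `read_probability_series()` returns the tibble.
#' @export
write_probability_series <- function(series, path) {
  need <- c("participant_id", "date", "minute", "provisional", "final")
  if (!all(need %in% names(series))) {
    abort(sprintf("probability series needs columns %s", paste(need, collapse = ", ")))
  }
  contiguous <- series |>
    group_by(.data$participant_id, .data$date) |>
    summarise(ok = all(diff(sort(.data$minute)) == 1), .groups = "drop")
  if (nrow(series) && !all(contiguous$ok)) {
    abort("probability series minutes must be contiguous within each day")
  }
  readr::write_csv(series[need], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_probability_series
#' @export
read_probability_series <- function(path) {
  read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), date = readr::col_date(),
    minute = readr::col_integer(), provisional = readr::col_double(),
    final = readr::col_double()
  ))
}

#' Write / read a training feature matrix
#'
#' One row per labelled 1800-second window:
#' `participant_id,date,window_start,label,<app>_f1..f5`. Missing reaction
#' features are written as empty cells.
#'
#' @param features Tibble from [build_training_set()].
#' @param path Destination CSV path.
#' @param tz Local time zone (for reading).
#' @export
write_features <- function(features, path) {
  out <- features
  out$window_start <- format_ts(out$window_start)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path, tz = "Asia/Taipei") {
  x <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), date = readr::col_date(),
    window_start = readr::col_character(), label = readr::col_integer(),
    .default = readr::col_double()
  ))
  x$window_start <- parse_ts(x$window_start, tz, path)
  x
}

#' Write / read a day segmentation
#'
#' Minute states are stored as `participant_id,date,minute,state` with
#' states `office`, `break_at_work`, `off`, `remote`.
#'
#' @param seg Tibble with at least those four columns.
#' @param path Destination CSV path.
#' @export
write_segmentation <- function(seg, path) {
  readr::write_csv(seg[c("participant_id", "date", "minute", "state")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_segmentation
#' @export
read_segmentation <- function(path) {
  read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), date = readr::col_date(),
    minute = readr::col_integer(), state = readr::col_character()
  ))
}

#' Write / read ground-truth schedules
#'
#' Simulated truth is stored as `participant_id,date,minute,state,day_type`.
#' @param truth Ground-truth tibble from [simulate_days()].
#' @param path Destination CSV path.
#' @export
write_truth <- function(truth, path) {
  readr::write_csv(truth, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), date = readr::col_date(),
    minute = readr::col_integer(), state = readr::col_character(),
    day_type = readr::col_character()
  ))
}

#' Write / read GPS-defined work hours
#'
#' One row per work interval: `participant_id,date,start,end,day_class`;
#' days without any interval (holidays) get a single row with empty
#' start/end.
#'
#' @param intervals Interval tibble from [label_work_intervals()].
#' @param days Day-class tibble from [classify_days()].
#' @param path Destination CSV path.
#' @param tz Local time zone (for reading).
#' @export
write_workhours <- function(intervals, days, path) {
  rows <- days |>
    left_join(intervals, by = c("participant_id", "date")) |>
    mutate(start = ifelse(is.na(.data$start), "", format_ts(.data$start)),
           end = ifelse(is.na(.data$end), "", format_ts(.data$end))) |>
    select("participant_id", "date", "start", "end", "day_class")
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_workhours
#' @export
read_workhours <- function(path, tz = "Asia/Taipei") {
  x <- read_csv_quiet(path, readr::cols(
    participant_id = readr::col_character(), date = readr::col_date(),
    start = readr::col_character(), end = readr::col_character(),
    day_class = readr::col_character()
  ))
  x$start <- ifelse(nzchar(x$start), x$start, NA)
  x$end <- ifelse(nzchar(x$end), x$end, NA)
  x$start <- lubridate::with_tz(suppressWarnings(lubridate::ymd_hms(x$start, tz = "UTC", quiet = TRUE)), tz)
  x$end <- lubridate::with_tz(suppressWarnings(lubridate::ymd_hms(x$end, tz = "UTC", quiet = TRUE)), tz)
  x
}
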
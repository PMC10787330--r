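# Small builders used across tests. All fixtures are generated in code.

TZ <- "Asia/Taipei"

ts_at <- function(x, tz = TZ) as.POSIXct(x, tz = tz)

mk_events <- function(times, kinds, apps, pid = "T01", tz = TZ) {
  tibble::tibble(participant_id = pid, timestamp = ts_at(times, tz),
                 kind = kinds, app_label = apps)
}

mk_gps <- function(times, lat, lon, pid = "T01", tz = TZ) {
  tibble::tibble(participant_id = pid, timestamp = ts_at(times, tz),
                 lat = lat, lon = lon)
}

# GPS track for one day at 600-s cadence: at `wp` during [work_start_s,
# work_end_s), at `home` otherwise (no commute, no noise)
mk_day_track <- function(date = "2022-03-01", work_start_s, work_end_s,
                         wp = c(25.06, 121.58), home = c(25.00, 121.50),
                         pid = "T01", tz = TZ) {
  secs <- seq(0, 86399, by = 600)
  at_work <- secs >= work_start_s & secs < work_end_s
  tibble::tibble(
    participant_id = pid,
    timestamp = ts_at(paste(date, "00:00:00"), tz) + secs,
    lat = ifelse(at_work, wp[1], home[1]),
    lon = ifelse(at_work, wp[2], home[2])
  )
}

# minute-state tibble on the standard grid from a 0/1 function of minute
mk_minutes <- function(date = "2022-03-01", at_fun, pid = "T01") {
  m <- 345:1439
  tibble::tibble(participant_id = pid, date = as.Date(date), minute = m,
                 at_work = as.integer(at_fun(m)))
}

mk_prob <- function(date = "2022-03-01", p, pid = "T01") {
  m <- 345:1439
  stopifnot(length(p) == length(m))
  tibble::tibble(participant_id = pid, date = as.Date(date), minute = m,
                 provisional = p, final = p)
}

# fast sim config: a single quiet app, no responses -- schedules only
quiet_sim <- function(...) {
  sim_config(apps = "app1", notif_rate_on = 0, notif_rate_off = 0,
             resp_prob_on = 0, resp_prob_off = 0,
             spont_rate_on = 0, spont_rate_off = 0, ...)
}

tiny_cnn <- function(...) {
  args <- list(lookback_min = 20L, kernels = c(5L, 3L, 2L),
               filters = c(2L, 3L, 2L), fc_width = 3L, epochs = 8L,
               patience = 3L, batch_size = 64L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cnn_config, args)
}
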
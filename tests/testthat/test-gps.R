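test_that("haversine distance has the right geometry", {
  expect_equal(haversine_km(25.03, 121.56, 25.03, 121.56), 0)
  # one degree of longitude on the equator with R = 6371 km
  expect_equal(haversine_km(0, 0, 0, 1), 6371 * pi / 180, tolerance = 1e-6)
  set.seed(1)
  a <- cbind(runif(50, -90, 90), runif(50, -180, 180))
  b <- cbind(runif(50, -90, 90), runif(50, -180, 180))
  expect_equal(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]),
               haversine_km(b[, 1], b[, 2], a[, 1], a[, 2]))
  expect_true(all(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]) >= 0))
  # independent reference on the same sphere radius
  skip_if_not_installed("geosphere")
  ref <- geosphere::distHaversine(a[, c(2, 1)], b[, c(2, 1)], r = 6371000) / 1000
  expect_equal(haversine_km(a[, 1], a[, 2], b[, 1], b[, 2]), ref,
               tolerance = 1e-9)
})

test_that("work intervals follow the geofence dwell rules", {
  cfg <- pipeline_config()
  wp <- tibble::tibble(lat = 25.06, lon = 121.58)

  # all fixes far away -> no interval
  far <- mk_day_track(work_start_s = 0, work_end_s = 0)
  expect_equal(nrow(label_work_intervals(far, wp, cfg)), 0)

  # in range 09:00-17:00 -> one interval backdated to the first in-range fix
  day <- mk_day_track(work_start_s = 9 * 3600, work_end_s = 17 * 3600 + 1)
  iv <- label_work_intervals(day, wp, cfg)
  expect_equal(nrow(iv), 1)
  expect_equal(format(iv$start, "%H:%M"), "09:00")
  expect_equal(format(iv$end, "%H:%M"), "17:00")

  # a short out-of-range excursion (12:00 and 12:10 fixes) does not split
  exc <- day
  out <- format(exc$timestamp, "%H:%M") %in% c("12:00", "12:10")
  exc$lat[out] <- 25.00; exc$lon[out] <- 121.50
  iv2 <- label_work_intervals(exc, wp, cfg)
  expect_equal(nrow(iv2), 1)
  expect_equal(format(iv2$start, "%H:%M"), "09:00")
  expect_equal(format(iv2$end, "%H:%M"), "17:00")

  # a 30-minute out-of-range run (4 fixes spanning 1800 s) does split
  exc2 <- day
  out2 <- format(exc2$timestamp, "%H:%M") %in% c("12:00", "12:10", "12:20", "12:30")
  exc2$lat[out2] <- 25.00; exc2$lon[out2] <- 121.50
  iv3 <- label_work_intervals(exc2, wp, cfg)
  expect_equal(nrow(iv3), 2)
  expect_equal(format(iv3$end[1], "%H:%M"), "11:50")
  expect_equal(format(iv3$start[2], "%H:%M"), "12:40")

  # a silent gap longer than the confirmation closes the interval
  gap <- day[!(format(day$timestamp, "%H:%M") >= "12:00" &
                 format(day$timestamp, "%H:%M") < "13:00"), ]
  iv4 <- label_work_intervals(gap, wp, cfg)
  expect_equal(nrow(iv4), 2)

  expect_error(label_work_intervals(day, wp[0, ], cfg), "workplace")
})

test_that("interval labeling matches an exhaustive run-scan on random tracks", {
  cfg <- pipeline_config()
  wp <- tibble::tibble(lat = 25.06, lon = 121.58)
  set.seed(42)
  for (rep in 1:100) {
    n <- sample(20:80, 1)
    secs <- sort(sample(seq(0, 86399, by = 60), n))
    # random in/out state with some persistence, random fix dropout
    state <- numeric(n); state[1] <- rbinom(1, 1, 0.5)
    for (i in 2:n) state[i] <- if (runif(1) < 0.85) state[i - 1] else 1 - state[i - 1]
    g <- tibble::tibble(
      participant_id = "T01",
      timestamp = ts_at("2022-03-01 00:00:00") + secs,
      lat = ifelse(state == 1, 25.06, 25.00),
      lon = ifelse(state == 1, 121.58, 121.50)
    )
    got <- label_work_intervals(g, wp, cfg)
    want <- oracle_intervals(secs, state == 1, cfg$confirm_s)
    expect_equal(nrow(got), length(want), info = sprintf("track %d", rep))
    if (length(want)) {
      wm <- do.call(rbind, want)
      day0 <- as.numeric(ts_at("2022-03-01 00:00:00"))
      expect_equal(as.numeric(got$start) - day0, wm[, 1],
                   info = sprintf("track %d starts", rep))
      expect_equal(as.numeric(got$end) - day0, wm[, 2],
                   info = sprintf("track %d ends", rep))
    }
  }
})

test_that("minute rasterisation counts interval minutes exactly", {
  cfg <- pipeline_config()
  d <- as.Date("2022-03-01")
  none <- minute_gps_state(tibble::tibble(participant_id = character(),
                                          date = as.Date(character()),
                                          start = ts_at(character()),
                                          end = ts_at(character())),
                           dates = d, participant_id = "T01", cfg = cfg)
  expect_equal(nrow(none), 1095)
  expect_true(all(none$at_work == 0))

  iv <- tibble::tibble(participant_id = "T01", date = d,
                       start = ts_at("2022-03-01 09:00:00"),
                       end = ts_at("2022-03-01 17:00:00"))
  ms <- minute_gps_state(iv, d, "T01", cfg)
  expect_equal(sum(ms$at_work), 480)

  # random interval sets against a direct membership test
  set.seed(7)
  for (rep in 1:20) {
    k <- sample(1:4, 1)
    s <- sort(sample(0:86000, k))
    e <- pmin(s + sample(600:14400, k, replace = TRUE), 86400)
    keep <- c(TRUE, s[-1] > e[-k])  # keep disjoint subset
    s <- s[keep]; e <- e[keep]
    ivr <- tibble::tibble(participant_id = "T01", date = d,
                          start = ts_at("2022-03-01 00:00:00") + s,
                          end = ts_at("2022-03-01 00:00:00") + e)
    msr <- minute_gps_state(ivr, d, "T01", cfg)
    m <- 345:1439
    direct <- vapply(m, function(mm) {
      any(mm * 60 < e & (mm + 1) * 60 > s)
    }, logical(1))
    expect_equal(msr$at_work, as.integer(direct))
  }
})

test_that("day classification follows the typical-workday criteria", {
  cfg <- pipeline_config()
  d <- as.Date("2022-03-01")
  mk_iv <- function(s, e) {
    if (!length(s)) {
      return(tibble::tibble(participant_id = character(), date = as.Date(character()),
                            start = ts_at(character()), end = ts_at(character())))
    }
    tibble::tibble(participant_id = "T01", date = d,
                   start = ts_at(paste("2022-03-01", s)),
                   end = ts_at(paste("2022-03-01", e)))
  }
  ms_of <- function(iv) minute_gps_state(iv, d, "T01", cfg)

  expect_equal(classify_day(mk_iv(character(), character()),
                            ms_of(mk_iv(character(), character())), cfg),
               "holiday")
  iv_typ <- mk_iv("09:00:00", "17:00:00")
  expect_equal(classify_day(iv_typ, ms_of(iv_typ), cfg), "typical")
  iv_late <- mk_iv("13:00:00", "21:00:00")
  expect_equal(classify_day(iv_late, ms_of(iv_late), cfg), "other")
  iv_short <- mk_iv("09:00:00", "12:00:00")
  expect_equal(classify_day(iv_short, ms_of(iv_short), cfg), "other")
  iv_all <- mk_iv("05:00:00", "23:59:59")
  expect_equal(classify_day(iv_all, ms_of(iv_all), cfg), "other")
})

test_that("labeled intervals recover true worksite spans on noiseless simulation", {
  cfg <- pipeline_config()
  p <- generate_participant(9, sim_config(gps_noise_sd = 0))
  s <- simulate_days(p, 10, seed = 5)
  iv <- label_work_intervals(s$gps, p$workplaces, cfg)
  tr <- s$truth[s$truth$state %in% c("office", "break_at_work"), ]
  spans <- dplyr::summarise(dplyr::group_by(tr, date),
                            s0 = min(minute) * 60,
                            s1 = (max(minute) + 1) * 60)
  expect_equal(sort(unique(iv$date)), sort(spans$date))
  j <- dplyr::inner_join(iv, spans, by = "date")
  tol <- cfg$gps_cadence_s + cfg$confirm_s
  day0 <- as.numeric(ts_at(paste(j$date, "00:00:00")))
  expect_true(all(abs((as.numeric(j$start) - day0) - j$s0) <= tol))
  expect_true(all(abs((as.numeric(j$end) - day0) - j$s1) <= tol))
})
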
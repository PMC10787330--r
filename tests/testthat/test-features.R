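test_that("episodes are reconstructed from screen events", {
  ev <- mk_events(
    c("2022-03-01 20:00:00", "2022-03-01 20:10:00",
      "2022-03-01 20:10:05", "2022-03-01 20:25:05"),
    c("notification", "notification", "screen_on", "screen_off"),
    c("YouTube", "YouTube", "YouTube", "")
  )
  eps <- extract_episodes(ev, TZ)
  expect_equal(nrow(eps), 1)
  expect_equal(eps$app_label, "YouTube")
  expect_equal(as.numeric(eps$end - eps$start, units = "secs"), 900)
  expect_false(eps$open_end)

  expect_equal(nrow(extract_episodes(mk_events(character(), character(),
                                               character()), TZ)), 0)

  # trailing open episode closed at day end and flagged
  ev2 <- mk_events("2022-03-01 23:30:00", "screen_on", "app1")
  eps2 <- extract_episodes(ev2, TZ)
  expect_true(eps2$open_end)
  expect_equal(format(eps2$end, "%H:%M:%S"), "23:59:59")

  # screen_off with no open episode is dropped with a warning
  ev3 <- mk_events(c("2022-03-01 10:00:00", "2022-03-01 11:00:00",
                     "2022-03-01 11:10:00"),
                   c("screen_off", "screen_on", "screen_off"),
                   c("", "app1", ""))
  expect_warning(eps3 <- extract_episodes(ev3, TZ), "no open episode")
  expect_equal(nrow(eps3), 1)
})

test_that("random event interleavings match the stack-matcher reference", {
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(4:30, 1)
    secs <- sort(sample(3600:80000, n))
    kinds <- sample(c("screen_on", "screen_off"), n, replace = TRUE)
    apps <- ifelse(kinds == "screen_on",
                   sample(c("a", "b"), n, replace = TRUE), "")
    ev <- tibble::tibble(participant_id = "T01",
                         timestamp = ts_at("2022-03-01 00:00:00") + secs,
                         kind = kinds, app_label = apps)
    got <- suppressWarnings(extract_episodes(ev, TZ))
    got <- got[!got$open_end, ]
    want <- oracle_episodes(kinds, secs, apps)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      wm <- do.call(rbind, want)
      day0 <- as.numeric(ts_at("2022-03-01 00:00:00"))
      expect_equal(sort(as.numeric(got$start) - day0), sort(wm[, 1]))
      expect_equal(sort(as.numeric(got$end) - day0), sort(wm[, 2]))
    }
  }
})

test_that("the phone-call worked example gives reaction time 1 s, intensity 900 s", {
  ev <- mk_events(
    c("2022-03-01 10:00:00", "2022-03-01 10:00:01", "2022-03-01 10:15:01"),
    c("notification", "screen_on", "screen_off"),
    c("Phone", "Phone", "")
  )
  eps <- extract_episodes(ev, TZ)
  w <- compute_window_features(eps, ev[ev$kind == "notification", ],
                               ts_at("2022-03-01 10:00:00"), vocab = "Phone",
                               tz = TZ)
  expect_equal(w$Phone_f4, 1)
  expect_equal(w$Phone_f5, 900)
})

test_that("the YouTube worked example gives the feature vector (900, 0, 2, 5, 900)", {
  ev <- mk_events(
    c("2022-03-01 20:00:00", "2022-03-01 20:10:00",
      "2022-03-01 20:10:05", "2022-03-01 20:25:05"),
    c("notification", "notification", "screen_on", "screen_off"),
    c("YouTube", "YouTube", "YouTube", "")
  )
  eps <- extract_episodes(ev, TZ)
  w <- compute_window_features(eps, ev[ev$kind == "notification", ],
                               ts_at("2022-03-01 20:00:00"), vocab = "YouTube",
                               tz = TZ)
  expect_equal(unname(unlist(w)), c(900, 0, 2, 5, 900))
})

test_that("an empty window has zero counts and missing reaction features", {
  w <- compute_window_features(
    extract_episodes(mk_events(character(), character(), character()), TZ),
    mk_events(character(), character(), character()),
    ts_at("2022-03-01 10:00:00"), vocab = c("a", "b"), tz = TZ
  )
  expect_equal(unname(unlist(w[c("a_f1", "a_f2", "a_f3")])), c(0, 0, 0))
  expect_true(is.na(w$a_f4) && is.na(w$b_f5))
  expect_equal(ncol(w), 10)
  expect_error(
    compute_window_features(NULL, NULL, ts_at("2022-03-01 10:00:00"),
                            "a", window_s = 900),
    "1800"
  )
})

test_that("window features equal brute-force interval arithmetic on random windows", {
  set.seed(23)
  vocab <- c("a", "b")
  n_checked <- 0
  for (rep in 1:50) {
    # one synthetic day of episodes and notifications per replicate
    k <- sample(5:15, 1)
    s0 <- sort(sample(21600:80000, k))
    len <- sample(30:2400, k, replace = TRUE)
    e0 <- pmin(s0 + len, 86000)
    s <- c(); e <- c()
    for (i in seq_len(k)) {   # keep a disjoint subset (episodes never overlap)
      if (!length(e) || s0[i] >= e[length(e)]) {
        s <- c(s, s0[i]); e <- c(e, max(e0[i], s0[i] + 1))
      }
    }
    app <- sample(vocab, length(s), replace = TRUE)
    nn <- sample(5:20, 1)
    nt <- sort(sample(21600:84000, nn))
    napp <- sample(vocab, nn, replace = TRUE)

    episodes <- tibble::tibble(
      participant_id = "T01", date = as.Date("2022-03-01"), app_label = app,
      start = ts_at("2022-03-01 00:00:00") + s,
      end = ts_at("2022-03-01 00:00:00") + e, open_end = FALSE
    )
    notifs <- tibble::tibble(
      participant_id = "T01",
      timestamp = ts_at("2022-03-01 00:00:00") + nt,
      kind = "notification", app_label = napp
    )
    for (a0 in sample(seq(21600, 82800, by = 60), 20)) {
      got <- compute_window_features(episodes, notifs,
                                     ts_at("2022-03-01 00:00:00") + a0,
                                     vocab, tz = TZ)
      want <- oracle_window_features(
        data.frame(app = app, s = s, e = e),
        data.frame(app = napp, sec = nt), a0, a0 + 1800, vocab
      )
      expect_equal(unlist(got), want, tolerance = 1e-9)
      n_checked <- n_checked + 1
      # structural invariants
      expect_true(all(unlist(got[paste0(vocab, "_f1")]) <= 1800))
      tot <- vapply(vocab, function(v) sum(napp == v & nt >= a0 & nt < a0 + 1800),
                    numeric(1))
      expect_equal(unname(unlist(got[paste0(vocab, "_f2")]) +
                            unlist(got[paste0(vocab, "_f3")])), unname(tot))
    }
  }
  expect_equal(n_checked, 1000)
})

test_that("training windows honour all exclusion rules", {
  cfg <- pipeline_config()
  d <- as.Date("2022-03-01")
  # work 09:10-17:20 so the transitions straddle aligned windows
  ms <- mk_minutes(at_fun = function(m) m >= 550 & m < 1040)
  days <- tibble::tibble(participant_id = "T01", date = d,
                         day_class = "typical", work_h = 8.2)
  ev <- mk_events(
    c("2022-03-01 10:00:00", "2022-03-01 10:00:30", "2022-03-01 21:00:00",
      "2022-03-01 21:05:00"),
    c("screen_on", "screen_off", "screen_on", "screen_off"),
    c("a", "", "a", "")
  )
  tr <- build_training_set(ev, ms, days, cfg)
  # enumeration: aligned starts 06:00..23:30 = 36 windows, minus the two
  # mixed windows [09:00,09:30) and [17:00,17:30)
  expect_equal(nrow(tr), 34)
  starts_h <- as.integer(format(tr$window_start, "%H")) +
    as.integer(format(tr$window_start, "%M")) / 60
  expect_false(any(starts_h < 6))            # nightly exclusion
  expect_false(any(starts_h %in% c(9, 17)))  # mixed-label windows dropped
  expect_equal(sum(tr$label), sum(starts_h >= 9.5 & starts_h < 17))

  # a non-typical day contributes nothing
  days_h <- dplyr::mutate(days, day_class = "holiday")
  expect_error(build_training_set(ev, ms, days_h, cfg), "typical")

  # a day without screen events is excluded
  ev_notif <- mk_events("2022-03-01 10:00:00", "notification", "a")
  expect_error(build_training_set(ev_notif, ms, days, cfg),
               "typical workday with screen events")
})

test_that("imputation resamples observed values only", {
  df <- tibble::tibble(x = c(1, NA, 3, NA), y = c(NA, 2, 2, 2))
  imp <- impute_missing(df, seed = 1)
  expect_false(anyNA(imp))
  expect_true(all(imp$x %in% c(1, 3)))
  expect_true(all(imp$y == 2))
  expect_identical(impute_missing(df, seed = 5), impute_missing(df, seed = 5))

  intact <- tibble::tibble(x = 1:3)
  expect_identical(impute_missing(intact, seed = 1), intact)

  expect_error(impute_missing(tibble::tibble(x = c(NA_real_, NA_real_))),
               "no observed value")

  # reference pool from training data only
  ref <- list(x = c(10, 10))
  imp2 <- impute_missing(tibble::tibble(x = c(NA_real_, 1)), ref, seed = 2)
  expect_equal(imp2$x, c(10, 1))

  set.seed(99)
  for (rep in 1:20) {
    m <- tibble::tibble(a = ifelse(runif(30) < 0.3, NA, rnorm(30)),
                        b = ifelse(runif(30) < 0.3, NA, rnorm(30)))
    if (all(is.na(m$a)) || all(is.na(m$b))) next
    got <- impute_missing(m, seed = rep)
    expect_true(all(got$a %in% m$a[!is.na(m$a)] | !is.na(m$a)))
    expect_true(all(got$b %in% m$b[!is.na(m$b)] | !is.na(m$b)))
  }
})
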
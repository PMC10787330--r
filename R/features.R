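# Five features per app per 1800-s window:
#   f1 usage_duration_s        seconds of app usage clipped to the window
#   f2 notif_in_episode_count  notifications arriving inside that app's episodes
#   f3 notif_outside_count     notifications arriving outside episodes
#   f4 reaction_time_s         mean delay from the triggering notification to
#                              the start of the usage episode, over episodes
#                              starting in the window
#   f5 reaction_intensity_s    mean duration of those notification-triggered
#                              episodes
# The triggering notification of an episode is the most recent same-app
# notification arriving after the previous episode of that app ended and
# before this episode started; an episode can absorb several notifications,
# and the delay is measured from the latest one.

#' Reconstruct app usage episodes
#'
#' Pairs every `screen_on` with the next `screen_off` of the same
#' participant-day. A `screen_on` while an episode is already open closes
#' the running episode at the new start (a zero-gap app switch); a
#' `screen_off` with no open episode is dropped with a warning; an episode
#' still open at the end of a day is closed at 23:59:59 and flagged.
#'
#' @param events Event tibble (sorted; see [read_events()]).
#' @param tz Local time zone.
#' @return Tibble `participant_id, date, app_label, start, end, open_end`.
#' @export
extract_episodes <- function(events, tz = "Asia/Taipei") {
  empty <- tibble(participant_id = character(), date = as.Date(character()),
                  app_label = character(),
                  start = as.POSIXct(character(), tz = tz),
                  end = as.POSIXct(character(), tz = tz), open_end = logical())
  if (nrow(events) == 0) return(empty)
  ev <- events[events$kind %in% c("screen_on", "screen_off"), ]
  if (nrow(ev) == 0) return(empty)
  ev$date <- local_date(ev$timestamp, tz)
  parts <- split(ev, list(ev$participant_id, ev$date), drop = TRUE)
  out <- map(parts, function(g) {
    g <- g[order(g$timestamp, .KIND_PRIORITY[g$kind]), ]
    open_app <- NULL; open_t <- NULL
    eps <- list(); dropped <- 0L
    for (i in seq_len(nrow(g))) {
      if (g$kind[i] == "screen_on") {
        if (!is.null(open_app)) {
          eps[[length(eps) + 1L]] <- list(app = open_app, s = open_t,
                                          e = g$timestamp[i], open = FALSE)
        }
        open_app <- g$app_label[i]; open_t <- g$timestamp[i]
      } else {
        if (is.null(open_app)) {
          dropped <- dropped + 1L
        } else {
          eps[[length(eps) + 1L]] <- list(app = open_app, s = open_t,
                                          e = g$timestamp[i], open = FALSE)
          open_app <- NULL
        }
      }
    }
    if (!is.null(open_app)) {
      day_end <- as.POSIXct(paste(g$date[1], "23:59:59"), tz = tz)
      eps[[length(eps) + 1L]] <- list(app = open_app, s = open_t,
                                      e = day_end, open = TRUE)
    }
    if (dropped > 0) {
      warn(sprintf("%s %s: dropped %d screen_off event(s) with no open episode",
                   g$participant_id[1], g$date[1], dropped))
    }
    if (!length(eps)) return(NULL)
    tibble(
      participant_id = g$participant_id[1], date = g$date[1],
      app_label = map_chr(eps, "app"),
      start = as.POSIXct(map_dbl(eps, ~ as.numeric(.x$s)), tz = tz, origin = "1970-01-01"),
      end = as.POSIXct(map_dbl(eps, ~ as.numeric(.x$e)), tz = tz, origin = "1970-01-01"),
      open_end = map_lgl(eps, "open")
    )
  })
  res <- list_rbind(out[!vapply(out, is.null, logical(1))])
  res <- res[as.numeric(res$end) > as.numeric(res$start), ]
  res[order(res$participant_id, res$start), ]
}

# Count of sorted values `v` strictly below each element of `x`
n_below <- function(x, v) findInterval(x - 1e-6, v)

# Vectorised per-day feature engine. `episodes`/`notifs` use seconds of day;
# `win_start` is a numeric vector of window starts (seconds of day).
# Returns a matrix n_windows x (5 * length(vocab)).
window_features_core <- function(episodes, notifs, win_start, vocab, window_s) {
  nw <- length(win_start)
  a <- win_start; b <- win_start + window_s
  out <- matrix(NA_real_, nw, 5L * length(vocab))
  colnames(out) <- as.vector(t(outer(vocab, paste0("_f", 1:5), paste0)))
  for (j in seq_along(vocab)) {
    app <- vocab[j]
    ep <- episodes[episodes$app == app, , drop = FALSE]
    tn <- sort(notifs$sec[notifs$app == app])
    cols <- (j - 1L) * 5L

    # merge any same-app overlaps so the occupancy function is well defined
    if (nrow(ep) > 1) {
      ep <- ep[order(ep$s), ]
      keep_s <- ep$s[1]; keep_e <- ep$e[1]; s_out <- c(); e_out <- c()
      for (i in seq_len(nrow(ep))[-1]) {
        if (ep$s[i] <= keep_e) keep_e <- max(keep_e, ep$e[i])
        else { s_out <- c(s_out, keep_s); e_out <- c(e_out, keep_e)
               keep_s <- ep$s[i]; keep_e <- ep$e[i] }
      }
      s <- c(s_out, keep_s); e <- c(e_out, keep_e)
    } else { s <- ep$s; e <- ep$e }

    # f1: occupancy integral difference
    if (length(s)) {
      cum <- cumsum(e - s)
      occ <- function(t) {
        k <- findInterval(t, s)
        ifelse(k == 0, 0, cum[pmax(k, 1)] - pmax(0, e[pmax(k, 1)] - t))
      }
      out[, cols + 1L] <- occ(b) - occ(a)
    } else out[, cols + 1L] <- 0

    # f2/f3: notifications inside vs outside episodes
    if (length(tn)) {
      k <- findInterval(tn, if (length(s)) s else numeric())
      inside <- k > 0 & tn < (if (length(e)) e[pmax(k, 1)] else Inf)
      t_in <- tn[inside]; t_out <- tn[!inside]
      out[, cols + 2L] <- n_below(b, t_in) - n_below(a, t_in)
      out[, cols + 3L] <- n_below(b, t_out) - n_below(a, t_out)
    } else {
      out[, cols + 2L] <- 0; out[, cols + 3L] <- 0
    }

    # f4/f5: notification -> episode pairs, keyed by episode start
    if (length(s) && length(tn)) {
      prev_end <- c(0, e[-length(e)])
      ki <- findInterval(s - 1e-6, tn)       # latest notification < start
      has <- ki > 0 & tn[pmax(ki, 1)] >= prev_end
      ps <- s[has]
      if (length(ps)) {
        rt <- ps - tn[ki[has]]
        it <- (e - s)[has]
        crt <- cumsum(rt); cit <- cumsum(it)
        cnt_b <- n_below(b, ps); cnt_a <- n_below(a, ps)
        npair <- cnt_b - cnt_a
        sum_at <- function(cs, k) ifelse(k == 0, 0, cs[pmax(k, 1)])
        mrt <- (sum_at(crt, cnt_b) - sum_at(crt, cnt_a)) / npair
        mit <- (sum_at(cit, cnt_b) - sum_at(cit, cnt_a)) / npair
        mrt[npair == 0] <- NA_real_; mit[npair == 0] <- NA_real_
        out[, cols + 4L] <- mrt; out[, cols + 5L] <- mit
      }
    }
  }
  out
}

# split POSIXct episode/notification tables into per-day seconds
day_tables <- function(episodes, notifications, date, tz) {
  ep <- episodes[episodes$date == date, , drop = FALSE]
  list(
    episodes = tibble(app = ep$app_label,
                      s = seconds_of_day(ep$start, tz),
                      e = ifelse(local_date(ep$end, tz) > date, 86400,
                                 seconds_of_day(ep$end, tz))),
    notifs = {
      nt <- notifications[local_date(notifications$timestamp, tz) == date, , drop = FALSE]
      tibble(app = nt$app_label, sec = seconds_of_day(nt$timestamp, tz))
    }
  )
}

#' Compute the five-feature block of one window
#'
#' Evaluates the per-app feature scheme on a single 1800-second window.
#'
#' @param episodes Episode tibble from [extract_episodes()].
#' @param notifications Event tibble rows with `kind == "notification"`.
#' @param window_start POSIXct start of the window.
#' @param vocab Character vector: the app vocabulary (feature space).
#' @param window_s Window length; must be 1800.
#' @param tz Local time zone.
#' @return A one-row tibble with columns `<app>_f1` .. `<app>_f5`;
#'   reaction features are `NA` when no notification-triggered episode
#'   starts in the window.
#' @export
compute_window_features <- function(episodes, notifications, window_start,
                                    vocab, window_s = 1800,
                                    tz = "Asia/Taipei") {
  if (window_s != 1800) abort("the feature window must be 1800 seconds")
  d <- local_date(window_start, tz)
  dt <- day_tables(episodes, notifications, d, tz)
  m <- window_features_core(dt$episodes, dt$notifs,
                            seconds_of_day(window_start, tz), vocab, window_s)
  as_tibble(as.data.frame(m))
}

#' App vocabulary of an event stream
#'
#' The sorted set of non-empty app labels seen on the given days (from
#' `screen_on` and `notification` events). The vocabulary fixes the feature
#' space of a participant's model; apps unseen at training time are ignored
#' at inference.
#'
#' @param events Event tibble.
#' @param dates Optional restriction to training dates.
#' @param tz Local time zone.
#' @export
app_vocabulary <- function(events, dates = NULL, tz = "Asia/Taipei") {
  ev <- events[events$kind %in% c("screen_on", "notification"), ]
  if (!is.null(dates)) ev <- ev[local_date(ev$timestamp, tz) %in% dates, ]
  sort(unique(ev$app_label[nzchar(ev$app_label)]))
}

#' Build the training feature matrix
#'
#' Converts typical workdays into labelled 1800-second windows. Windows are
#' aligned at an 1800-second stride from local midnight; windows touching
#' the nightly exclusion span (midnight-05:45), windows containing both
#' on-working and off-working minutes, and days without any screen event
#' are all excluded. Labels come from the GPS-defined minute states (1 =
#' on-working).
#'
#' @param events Event tibble for one participant.
#' @param minute_states Per-minute GPS states from [minute_gps_state()].
#' @param days Day-class tibble from [classify_days()]; only
#'   `day_class == "typical"` days contribute rows.
#' @param cfg A [pipeline_config()].
#' @param vocab App vocabulary; defaults to the apps seen on the typical
#'   days.
#' @return Tibble `participant_id, date, window_start, label, <app>_f1..f5`
#'   with the vocabulary in `attr(, "vocab")`. Errors if no window
#'   survives.
#' @export
build_training_set <- function(events, minute_states, days,
                               cfg = pipeline_config(), vocab = NULL) {
  tz <- cfg$tz
  typical <- days$date[days$day_class == "typical"]
  ev_dates <- local_date(events$timestamp, tz)
  has_screen <- sort(unique(ev_dates[events$kind %in% c("screen_on", "screen_off")]))
  use_dates <- intersect(typical, has_screen)
  use_dates <- as.Date(use_dates, origin = "1970-01-01")
  if (!length(use_dates)) abort("no typical workday with screen events to train on")
  if (is.null(vocab)) vocab <- app_vocabulary(events, use_dates, tz)
  if (!length(vocab)) abort("empty app vocabulary on the training days")

  episodes <- extract_episodes(events[ev_dates %in% use_dates, ], tz)
  notifications <- events[events$kind == "notification" & ev_dates %in% use_dates, ]
  night_end_s <- cfg$night_exclusion_min[2] * 60
  first_start <- ceiling(night_end_s / cfg$window_s) * cfg$window_s
  starts <- seq(first_start, 86400 - cfg$window_s, by = cfg$window_s)

  rows <- map(use_dates, function(d) {
    ms <- minute_states[minute_states$date == d, ]
    at <- setNames(ms$at_work, ms$minute)
    lab <- vapply(starts, function(s0) {
      mins <- (s0 %/% 60):((s0 + cfg$window_s) %/% 60 - 1L)
      v <- at[as.character(mins)]
      if (anyNA(v)) return(NA_integer_)
      if (all(v == 1L)) 1L else if (all(v == 0L)) 0L else NA_integer_
    }, integer(1))
    keep <- !is.na(lab)
    if (!any(keep)) return(NULL)
    dt <- day_tables(episodes, notifications, d, tz)
    m <- window_features_core(dt$episodes, dt$notifs, starts[keep], vocab, cfg$window_s)
    bind_cols(
      tibble(participant_id = events$participant_id[1], date = d,
             window_start = as.POSIXct(paste(d, "00:00:00"), tz = tz) + starts[keep],
             label = lab[keep]),
      as_tibble(as.data.frame(m))
    )
  })
  out <- list_rbind(rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) abort("no training window survived the exclusion rules")
  attr(out, "vocab") <- vocab
  out
}

#' Per-minute feature matrix for inference
#'
#' For every minute of the evaluated span (05:45-24:00) of each requested
#' day, computes the feature block of the 1800-second window ending at that
#' minute. This is the bridge from window-level training to minute-level
#' probability sequences.
#'
#' @inheritParams build_training_set
#' @param dates Days to featurise.
#' @param vocab App vocabulary of the fitted model.
#' @return Tibble `participant_id, date, minute, <features>`.
#' @export
minute_feature_matrix <- function(events, dates, vocab, cfg = pipeline_config()) {
  tz <- cfg$tz
  ev_dates <- local_date(events$timestamp, tz)
  episodes <- extract_episodes(events[ev_dates %in% dates, ], tz)
  notifications <- events[events$kind == "notification" & ev_dates %in% dates, ]
  pid <- if (nrow(events)) events$participant_id[1] else NA_character_
  rows <- map(dates, function(d) {
    dt <- day_tables(episodes, notifications, d, tz)
    ends <- .GRID_MIN * 60
    m <- window_features_core(dt$episodes, dt$notifs, ends - cfg$window_s,
                              vocab, cfg$window_s)
    bind_cols(tibble(participant_id = pid, date = d, minute = .GRID_MIN),
              as_tibble(as.data.frame(m)))
  })
  list_rbind(rows)
}

#' Impute missing feature values by resampling
#'
#' Replaces every missing value of a column by a draw (with replacement)
#' from that column's observed values — or from a reference set fitted on
#' training data, so no information leaks from held-out rows.
#'
#' @param data Data frame of feature columns (may contain `NA`).
#' @param reference Optional named list of observed-value vectors per
#'   column (from training data). Defaults to the observed values of
#'   `data` itself.
#' @param seed Integer seed; imputation is deterministic given it.
#' @return `data` with no missing values.
#' @export
impute_missing <- function(data, reference = NULL, seed = 1L) {
  cols <- names(data)[vapply(data, is.numeric, logical(1))]
  local_rng(seed, {
    for (cl in cols) {
      miss <- is.na(data[[cl]])
      if (!any(miss)) next
      pool <- if (!is.null(reference)) reference[[cl]] else data[[cl]][!miss]
      pool <- pool[!is.na(pool)]
      if (!length(pool)) {
        abort(sprintf("column %s has no observed value to impute from", shQuote(cl)))
      }
      data[[cl]][miss] <- pool[sample.int(length(pool), sum(miss), replace = TRUE)]
    }
    data
  })
}

# observed-value reference list for later imputation
impute_reference <- function(data) {
  cols <- names(data)[vapply(data, is.numeric, logical(1))]
  setNames(lapply(cols, function(cl) {
    v <- data[[cl]]
    v[!is.na(v)]
  }), cols)
}
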
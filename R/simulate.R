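# Synthetic cohort generator: event streams + GPS tracks with known
# minute-level ground truth, so the whole pipeline is testable end to end.

local_rng <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

# km offsets -> degree offsets at a given latitude
km_to_deg <- function(dkm_lat, dkm_lon, lat) {
  cbind(dkm_lat / 110.574, dkm_lon / (111.320 * cos(lat * pi / 180)))
}

#' Generate a synthetic participant profile
#'
#' Draws one participant from the population described by a [sim_config()]:
#' home and workplace coordinates, an app vocabulary, per-app notification
#' and spontaneous-usage rates in each behavioural regime, response
#' probabilities, reaction-time and episode-duration distributions, and a
#' work schedule. The configured `contrast` interpolates every off-regime
#' parameter between its on-regime value (contrast 0, regimes
#' indistinguishable) and the fully separated configuration value
#' (contrast 1).
#'
#' @param seed Integer seed; the same seed and config always yield the same
#'   profile.
#' @param config A [sim_config()].
#' @return A list of class `participant_profile`.
#' @examples
#' p <- generate_participant(1)
#' p$workplaces
#' @export
generate_participant <- function(seed, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (config$contrast < 0 || config$contrast > 1) {
    abort("`contrast` must lie in [0, 1]")
  }
  local_rng(seed, {
    n <- length(config$apps)
    mix <- function(on, off) on + config$contrast * (off - on)
    jit <- function(k) rlnorm(k, 0, config$participant_jitter_sdlog)

    rate_j <- jit(n); spont_j <- jit(n)
    rates <- tibble(
      app = config$apps,
      notif_on = config$notif_rate_on * rate_j,
      notif_off = mix(config$notif_rate_on, config$notif_rate_off) * rate_j,
      spont_on = config$spont_rate_on * spont_j,
      spont_off = mix(config$spont_rate_on, config$spont_rate_off) * spont_j,
      resp_on = config$resp_prob_on,
      resp_off = mix(config$resp_prob_on, config$resp_prob_off)
    )
    lognorm_pars <- function(median_s, sdlog, j) {
      on_m <- unname(median_s[["on"]]); off_m <- unname(median_s[["off"]])
      on_s <- unname(sdlog[["on"]]); off_s <- unname(sdlog[["off"]])
      list(on = c(median = on_m * j, sdlog = on_s),
           off = c(median = exp(mix(log(on_m), log(off_m))) * j,
                   sdlog = mix(on_s, off_s)))
    }
    rt <- lognorm_pars(config$rt_median_s, config$rt_sdlog, jit(1))
    episode <- lognorm_pars(config$episode_median_s, config$episode_sdlog, jit(1))

    home <- c(lat = config$home_lat + rnorm(1, 0, 0.02),
              lon = config$home_lon + rnorm(1, 0, 0.02))
    wp_off <- km_to_deg(
      rnorm(config$n_workplaces, 4, 1.5), rnorm(config$n_workplaces, 3, 1.5),
      home["lat"]
    )
    workplaces <- tibble(lat = unname(home["lat"]) + wp_off[, 1],
                         lon = unname(home["lon"]) + wp_off[, 2])

    schedule <- list(
      work_start_mean_h = config$work_start_mean_h + rnorm(1, 0, 0.25),
      work_start_sd_h = config$work_start_sd_h,
      work_dur_mean_h = config$work_dur_mean_h + rnorm(1, 0, 0.4),
      work_dur_sd_h = config$work_dur_sd_h,
      breaks_lambda = config$breaks_lambda,
      break_len_median_min = config$break_len_median_min,
      break_len_sdlog = config$break_len_sdlog,
      remote_lambda = config$remote_lambda,
      remote_len_median_min = config$remote_len_median_min,
      remote_len_sdlog = config$remote_len_sdlog,
      holiday_prob = config$holiday_prob,
      commute_min = config$commute_min
    )

    profile <- structure(list(
      participant_id = sprintf("P%03d", as.integer(seed) %% 1000L),
      home = home, workplaces = workplaces, apps = config$apps,
      rates = rates, rt = rt, episode = episode, schedule = schedule,
      gps_noise_sd = config$gps_noise_sd, sleep_atten = config$sleep_atten,
      contrast = config$contrast, seed = as.integer(seed)
    ), class = "participant_profile")
    validate_profile(profile)
    profile
  })
}

#' Validate a participant profile
#'
#' Checks the structural invariants of a profile: at most five workplaces,
#' non-negative event rates, probabilities in `[0, 1]`, coordinates in
#' range and positive distribution parameters. Invisibly returns the
#' profile; aborts on the first violation.
#'
#' @param profile A `participant_profile`.
#' @export
validate_profile <- function(profile) {
  stopifnot(inherits(profile, "participant_profile"))
  if (nrow(profile$workplaces) < 1 || nrow(profile$workplaces) > 5) {
    abort("a profile must register between 1 and 5 workplaces")
  }
  r <- profile$rates
  if (any(c(r$notif_on, r$notif_off, r$spont_on, r$spont_off) < 0)) {
    abort("event rates must be non-negative")
  }
  if (any(c(r$resp_on, r$resp_off, profile$schedule$holiday_prob) < 0) ||
      any(c(r$resp_on, r$resp_off, profile$schedule$holiday_prob) > 1)) {
    abort("probabilities must lie in [0, 1]")
  }
  coords <- rbind(profile$workplaces[, c("lat", "lon")],
                  tibble(lat = profile$home[["lat"]], lon = profile$home[["lon"]]))
  if (any(abs(coords$lat) > 90) || any(abs(coords$lon) > 180)) {
    abort("coordinates out of range")
  }
  for (reg in c("on", "off")) {
    if (profile$rt[[reg]][["median"]] <= 0 || profile$episode[[reg]][["median"]] <= 0) {
      abort("log-normal medians must be positive")
    }
  }
  invisible(profile)
}

#' @export
print.participant_profile <- function(x, ...) {
  cat(sprintf("<participant_profile %s: %d apps, %d workplace(s), contrast %.2f>\n",
              x$participant_id, length(x$apps), nrow(x$workplaces), x$contrast))
  invisible(x)
}

# place non-overlapping episodes of given lengths (minutes) on free minutes
# of `state` matching `on_state`; returns modified state vector
place_episodes <- function(state, n, len_median, len_sdlog, lo, hi,
                           free = "office", mark = "break_at_work") {
  for (i in seq_len(n)) {
    len <- max(5L, round(rlnorm(1, log(len_median), len_sdlog)))
    if (hi - len <= lo) next
    for (try in 1:5) {
      st <- sample(lo:(hi - len), 1)
      idx <- (st + 1L):(st + len)
      if (all(state[idx] == free)) {
        state[idx] <- mark
        break
      }
    }
  }
  state
}

#' Simulate event and GPS streams for one participant
#'
#' Generates `n_days` of minute-resolved ground-truth states (office,
#' break at the worksite, off, remote working), a GPS track at the fixed
#' 600-second cadence with isotropic location noise and commute
#' interpolation between home and workplace, and a second-resolution screen
#' event stream: per-app Poisson notification arrivals whose rates depend on
#' the behavioural regime, log-normal reaction times for answered
#' notifications, and spontaneous usage episodes. The behavioural regime is
#' on-work during office and remote-working minutes and off-work otherwise,
#' so breaks look behaviourally like time off while GPS stays at the
#' worksite — exactly the signal the classifier must pick up.
#'
#' @param profile A `participant_profile`.
#' @param n_days Number of days to simulate (0 gives empty streams).
#' @param seed Integer seed for the participant's stream.
#' @param start_date First simulated date.
#' @param tz Local time zone of the participant.
#' @return A list with tibbles `events` (participant_id, timestamp, kind,
#'   app_label), `gps` (participant_id, timestamp, lat, lon) and `truth`
#'   (participant_id, date, minute, state, day_type).
#' @export
simulate_days <- function(profile, n_days, seed,
                          start_date = as.Date("2022-03-01"),
                          tz = "Asia/Taipei") {
  stopifnot(inherits(profile, "participant_profile"), n_days >= 0)
  empty <- list(
    events = tibble(participant_id = character(), timestamp = as.POSIXct(character(), tz = tz),
                    kind = character(), app_label = character()),
    gps = tibble(participant_id = character(), timestamp = as.POSIXct(character(), tz = tz),
                 lat = double(), lon = double()),
    truth = tibble(participant_id = character(), date = as.Date(character()),
                   minute = integer(), state = character(), day_type = character())
  )
  if (n_days == 0) return(empty)

  local_rng(participant_seed(seed, profile$participant_id), {
    days <- map(seq_len(n_days), function(d) {
      simulate_one_day(profile, start_date + d - 1L)
    })
    ev <- list_rbind(map(days, "events"))
    gp <- list_rbind(map(days, "gps"))
    tr <- list_rbind(map(days, "truth"))
    # to POSIXct in local tz; stable ordering with kind priority on ties
    if (nrow(ev)) {
      midnight <- as.POSIXct(paste(ev$date, "00:00:00"), tz = tz)
      pri <- c(notification = 0L, screen_off = 1L, screen_on = 2L)
      events <- tibble(
        participant_id = profile$participant_id,
        timestamp = midnight + ev$sec,
        kind = ev$kind, app_label = ev$app_label
      )
      events <- events[order(events$timestamp, pri[ev$kind]), ]
    } else {
      events <- empty$events
    }
    gps <- tibble(
      participant_id = profile$participant_id,
      timestamp = as.POSIXct(paste(gp$date, "00:00:00"), tz = tz) + gp$sec,
      lat = gp$lat, lon = gp$lon
    )
    truth <- tibble(participant_id = profile$participant_id,
                    date = tr$date, minute = tr$minute,
                    state = tr$state, day_type = tr$day_type)
    list(events = events, gps = gps, truth = truth)
  })
}

simulate_one_day <- function(profile, date) {
  sch <- profile$schedule
  state <- rep("off", 1440L)
  holiday <- runif(1) < sch$holiday_prob

  if (!holiday) {
    start_h <- rtrunc_norm(1, sch$work_start_mean_h, sch$work_start_sd_h, 6.5, 11.9)
    dur_h <- rtrunc_norm(1, sch$work_dur_mean_h, sch$work_dur_sd_h, 4.2, 14)
    end_h <- min(start_h + dur_h, 22.3)
    sm <- round(start_h * 60); em <- round(end_h * 60)
    state[(sm + 1L):em] <- "office"
    nb <- rpois(1, sch$breaks_lambda)
    state <- place_episodes(state, nb, sch$break_len_median_min, sch$break_len_sdlog,
                            lo = sm + 30L, hi = em - 10L,
                            free = "office", mark = "break_at_work")
    rem_lo <- em + sch$commute_min + 30L
  } else {
    sm <- em <- NA_integer_
    rem_lo <- 540L
  }
  nr <- rpois(1, sch$remote_lambda)
  state <- place_episodes(state, nr, sch$remote_len_median_min, sch$remote_len_sdlog,
                          lo = rem_lo, hi = 1410L, free = "off", mark = "remote")

  # GPS track at 600-s cadence; position follows the body, not the regime
  fix_sec <- seq(0, 86399, by = 600)
  wp <- c(profile$workplaces$lat[1], profile$workplaces$lon[1])
  home <- c(profile$home[["lat"]], profile$home[["lon"]])
  commute_s <- sch$commute_min * 60
  frac_at_work <- vapply(fix_sec, function(t) {
    if (holiday) return(0)
    start_s <- sm * 60; end_s <- em * 60
    if (t >= start_s && t < end_s) return(1)
    if (t >= start_s - commute_s && t < start_s) return((t - (start_s - commute_s)) / commute_s)
    if (t >= end_s && t < end_s + commute_s) return(1 - (t - end_s) / commute_s)
    0
  }, numeric(1))
  lat <- home[1] + frac_at_work * (wp[1] - home[1])
  lon <- home[2] + frac_at_work * (wp[2] - home[2])
  if (profile$gps_noise_sd > 0) {
    noise <- km_to_deg(rnorm(length(fix_sec), 0, profile$gps_noise_sd),
                       rnorm(length(fix_sec), 0, profile$gps_noise_sd), wp[1])
    lat <- lat + noise[, 1]; lon <- lon + noise[, 2]
  }
  gps <- tibble(date = date, sec = fix_sec, lat = lat, lon = lon)

  # behavioural regime per minute; sleep attenuation before 05:45
  regime <- ifelse(state %in% c("office", "remote"), "on", "off")
  atten <- ifelse(seq_len(1440L) - 1L < .NIGHT_END_MIN, profile$sleep_atten, 1)
  seg <- rle(paste(regime, atten))
  seg_end <- cumsum(seg$lengths)
  seg_start <- seg_end - seg$lengths           # minutes, 0-based
  seg_regime <- substr(seg$values, 1, 2) == "on"
  seg_atten <- atten[seg_start + 1L]

  ep <- list(); nt <- list()
  r <- profile$rates
  for (a in seq_along(profile$apps)) {
    for (s in seq_along(seg$lengths)) {
      reg <- if (seg_regime[s]) "on" else "off"
      dur_h <- seg$lengths[s] / 60
      t0 <- seg_start[s] * 60; t1 <- seg_end[s] * 60
      nrate <- (if (seg_regime[s]) r$notif_on[a] else r$notif_off[a]) * seg_atten[s]
      srate <- (if (seg_regime[s]) r$spont_on[a] else r$spont_off[a]) * seg_atten[s]
      kn <- rpois(1, nrate * dur_h)
      if (kn > 0) {
        tn <- sort(floor(runif(kn, t0, t1)))
        nt[[length(nt) + 1L]] <- tibble(app = profile$apps[a], sec = tn)
        presp <- if (seg_regime[s]) r$resp_on[a] else r$resp_off[a]
        resp <- runif(kn) < presp
        if (any(resp)) {
          rts <- rlnorm(sum(resp), log(profile$rt[[reg]][["median"]]),
                        profile$rt[[reg]][["sdlog"]])
          st <- floor(tn[resp] + rts)
          keep <- st < 86340
          if (any(keep)) {
            du <- rlnorm(sum(keep), log(profile$episode[[reg]][["median"]]),
                         profile$episode[[reg]][["sdlog"]])
            ep[[length(ep) + 1L]] <- tibble(
              app = profile$apps[a], start = st[keep],
              end = pmin(st[keep] + pmax(1, floor(du)), 86399)
            )
          }
        }
      }
      ks <- rpois(1, srate * dur_h)
      if (ks > 0) {
        st <- floor(runif(ks, t0, min(t1, 86340)))
        du <- rlnorm(ks, log(profile$episode[[reg]][["median"]]),
                     profile$episode[[reg]][["sdlog"]])
        ep[[length(ep) + 1L]] <- tibble(app = profile$apps[a], start = st,
                                        end = pmin(st + pmax(1, floor(du)), 86399))
      }
    }
  }
  episodes <- if (length(ep)) list_rbind(ep) else tibble(app = character(), start = double(), end = double())
  notifs <- if (length(nt)) list_rbind(nt) else tibble(app = character(), sec = double())

  # resolve episode overlaps: an app switch truncates the running episode
  if (nrow(episodes) > 1) {
    episodes <- episodes[order(episodes$start, episodes$end), ]
    episodes$end <- pmin(episodes$end, c(episodes$start[-1], Inf))
    episodes <- episodes[episodes$end > episodes$start, ]
  }

  ev <- bind_rows(
    tibble(date = date, sec = notifs$sec, kind = "notification", app_label = notifs$app),
    tibble(date = date, sec = episodes$start, kind = "screen_on", app_label = episodes$app),
    tibble(date = date, sec = episodes$end, kind = "screen_off", app_label = "")
  )
  truth <- tibble(date = date, minute = 0:1439, state = state,
                  day_type = if (holiday) "holiday" else "workday")
  list(events = ev, gps = gps, truth = truth)
}

#' Simulate a synthetic cohort
#'
#' Draws `n_participants` profiles with profile seeds `1..n_participants`
#' (so the cohort's behavioural population is fixed) and simulates each
#' participant's streams with an RNG stream derived from `seed` and the
#' participant id.
#'
#' @param n_participants Number of participants.
#' @param n_days Days per participant.
#' @param seed Global seed for the event/GPS streams.
#' @param config A [sim_config()].
#' @param start_date,tz Passed to [simulate_days()].
#' @return A tibble with one row per participant: `participant_id`,
#'   list-columns `profile`, `events`, `gps`, `truth`.
#' @export
simulate_cohort <- function(n_participants, n_days, seed,
                            config = sim_config(),
                            start_date = as.Date("2022-03-01"),
                            tz = "Asia/Taipei") {
  rows <- map(seq_len(n_participants), function(i) {
    profile <- generate_participant(i, config)
    profile$participant_id <- sprintf("P%03d", i)
    sim <- simulate_days(profile, n_days, seed, start_date, tz)
    tibble(participant_id = profile$participant_id,
           profile = list(profile), events = list(sim$events),
           gps = list(sim$gps), truth = list(sim$truth))
  })
  list_rbind(rows)
}
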
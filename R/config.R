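#' Pipeline configuration
#'
#' Bundles every numeric constant of the work-hour pipeline: the geofence
#' radius and dwell confirmation used to define GPS work hours, the feature
#' window length, the nightly exclusion span, the probability threshold that
#' separates on-working from off-working minutes, the transition exclusion
#' used during evaluation, the AUC discrimination floor, the greedy
#' feature-search tolerance and the minimum number of typical workdays a
#' participant must contribute.
#'
#' @param geofence_radius_km Radius (km) around a registered workplace within
#'   which a GPS fix counts as "at the worksite". Default 1.
#' @param confirm_s Dwell time (seconds) the device must stay continuously
#'   in range (or out of range) before work-hour recording starts (or stops).
#'   Default 1800.
#' @param gps_cadence_s Nominal GPS sampling interval in seconds. Default 600.
#' @param window_s Feature window length in seconds. Default 1800.
#' @param night_exclusion_min Two-element integer vector, minutes of day
#'   `[from, to)` excluded from training and evaluation. Default
#'   `c(0, 345)`, i.e. midnight to 05:45.
#' @param prob_threshold Probability above which a minute is interpreted as
#'   on-working. Default 0.5.
#' @param transition_exclusion_min Minutes masked on each side of a GPS
#'   on/off switch during evaluation. Default 15.
#' @param auc_floor AUC below which a participant's model is considered to
#'   have low discrimination. Default 0.7.
#' @param greedy_delta Maximum tolerated AUC loss when searching for a
#'   minimal feature subset. Default 0.01.
#' @param min_typical_days Minimum number of typical workdays required per
#'   participant. Default 5.
#' @param tz Time zone in which all wall-clock rules are interpreted.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(geofence_radius_km = 1.0,
                            confirm_s = 1800,
                            gps_cadence_s = 600,
                            window_s = 1800,
                            night_exclusion_min = c(0L, 345L),
                            prob_threshold = 0.5,
                            transition_exclusion_min = 15L,
                            auc_floor = 0.7,
                            greedy_delta = 0.01,
                            min_typical_days = 5L,
                            tz = "Asia/Taipei") {
  cfg <- list(
    geofence_radius_km = geofence_radius_km, confirm_s = confirm_s,
    gps_cadence_s = gps_cadence_s, window_s = window_s,
    night_exclusion_min = as.integer(night_exclusion_min),
    prob_threshold = prob_threshold,
    transition_exclusion_min = as.integer(transition_exclusion_min),
    auc_floor = auc_floor, greedy_delta = greedy_delta,
    min_typical_days = as.integer(min_typical_days), tz = tz
  )
  nums <- c(cfg$geofence_radius_km, cfg$confirm_s, cfg$gps_cadence_s,
            cfg$window_s, cfg$transition_exclusion_min, cfg$auc_floor,
            cfg$greedy_delta, cfg$min_typical_days)
  if (any(!is.finite(nums)) || any(nums <= 0)) {
    abort("all pipeline_config constants must be positive and finite")
  }
  if (cfg$prob_threshold <= 0 || cfg$prob_threshold >= 1) {
    abort("prob_threshold must lie in (0, 1)")
  }
  structure(cfg, class = "pipeline_config")
}

#' Simulator configuration
#'
#' Parameters of the synthetic cohort generator. The defaults are the
#' documented high-contrast profile: a population whose notification rates,
#' response probabilities, reaction times and app-usage episodes differ
#' sharply between the on-working regime (office or remote-working minutes)
#' and the off-working regime (breaks and time off). `contrast` in `[0, 1]`
#' interpolates the off-work regime parameters between the on-work values
#' (0: the two regimes are behaviourally identical, a null model) and the
#' fully separated defaults (1).
#'
#' Rates are events per hour per app, reaction-time and episode-duration
#' distributions are log-normal and parameterised by their median (seconds)
#' and log-scale dispersion, schedule times are hours of local wall-clock
#' time, break/remote lengths are minutes.
#'
#' @param apps Character vector of app labels (the app vocabulary).
#' @param notif_rate_on,notif_rate_off Per-app Poisson notification rates
#'   (events/hour) in each regime; must match `length(apps)`.
#' @param resp_prob_on,resp_prob_off Per-app probability of responding to a
#'   notification in each regime.
#' @param spont_rate_on,spont_rate_off Per-app rates of spontaneous
#'   (non-notification-triggered) usage episodes.
#' @param rt_median_s,rt_sdlog Reaction-time log-normal parameters per
#'   regime, named vectors `c(on = , off = )`.
#' @param episode_median_s,episode_sdlog Usage-episode duration parameters
#'   per regime.
#' @param work_start_mean_h,work_start_sd_h Work start-time distribution
#'   (truncated so starts fall before noon).
#' @param work_dur_mean_h,work_dur_sd_h Work duration distribution (hours).
#' @param breaks_lambda Mean number of break episodes per workday.
#' @param break_len_median_min,break_len_sdlog Break length distribution.
#' @param remote_lambda Mean number of evening remote-work episodes per day.
#' @param remote_len_median_min,remote_len_sdlog Remote episode length.
#' @param holiday_prob Probability that a day is a holiday (no worksite
#'   visit).
#' @param commute_min One-way commute duration in minutes.
#' @param gps_noise_sd Isotropic GPS noise standard deviation in km.
#' @param n_workplaces Number of registered workplaces (at most 5).
#' @param sleep_atten Multiplier applied to all event rates between midnight
#'   and 05:45 (people rarely touch the phone while asleep).
#' @param contrast Regime-contrast level in `[0, 1]`.
#' @param participant_jitter_sdlog Log-normal dispersion of per-participant
#'   multiplicative jitter applied to rates and medians.
#' @param home_lat,home_lon Cohort centre of home locations (degrees).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(apps = c("messenger", "email", "phone", "browser", "video"),
                       notif_rate_on  = c(4.0, 3.0, 1.0, 0.5, 0.2),
                       notif_rate_off = c(1.5, 0.3, 0.3, 2.0, 2.5),
                       resp_prob_on   = c(0.90, 0.80, 0.95, 0.30, 0.10),
                       resp_prob_off  = c(0.50, 0.20, 0.60, 0.70, 0.80),
                       spont_rate_on  = c(1.0, 1.5, 0.2, 0.3, 0.05),
                       spont_rate_off = c(1.0, 0.3, 0.1, 1.5, 1.2),
                       rt_median_s = c(on = 8, off = 90),
                       rt_sdlog = c(on = 0.7, off = 1.1),
                       episode_median_s = c(on = 45, off = 240),
                       episode_sdlog = c(on = 0.8, off = 1.0),
                       work_start_mean_h = 8.75, work_start_sd_h = 0.5,
                       work_dur_mean_h = 9, work_dur_sd_h = 0.75,
                       breaks_lambda = 1.5,
                       break_len_median_min = 35, break_len_sdlog = 0.4,
                       remote_lambda = 1.0,
                       remote_len_median_min = 50, remote_len_sdlog = 0.5,
                       holiday_prob = 0.25,
                       commute_min = 30,
                       gps_noise_sd = 0.05,
                       n_workplaces = 1L,
                       sleep_atten = 0.1,
                       contrast = 1.0,
                       participant_jitter_sdlog = 0.15,
                       home_lat = 25.03, home_lon = 121.56) {
  cfg <- mget(names(formals()))
  n <- length(apps)
  per_app <- list(notif_rate_on = notif_rate_on, notif_rate_off = notif_rate_off,
                  resp_prob_on = resp_prob_on, resp_prob_off = resp_prob_off,
                  spont_rate_on = spont_rate_on, spont_rate_off = spont_rate_off)
  for (nm in names(per_app)) {
    if (length(per_app[[nm]]) != n) {
      abort(sprintf("`%s` must have one value per app (%d)", nm, n))
    }
  }
  if (contrast < 0 || contrast > 1) {
    abort("`contrast` must lie in [0, 1] (0 = regimes identical, 1 = fully separated)")
  }
  if (n_workplaces < 1 || n_workplaces > 5) {
    abort("`n_workplaces` must be between 1 and 5: the app tracks at most 5 workplaces")
  }
  rates <- c(notif_rate_on, notif_rate_off, spont_rate_on, spont_rate_off)
  if (any(rates < 0)) abort("event rates must be non-negative")
  probs <- c(resp_prob_on, resp_prob_off, holiday_prob)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Temporal-model configuration
#'
#' Architecture and optimisation settings of the 1-D convolutional network
#' that smooths provisional per-minute probabilities. The structure is fixed
#' by construction: three convolution layers (the first two followed by
#' max pooling, the third by global average pooling) and two fully connected
#' layers, with rectified-linear hidden activations and a sigmoid output.
#' Filter counts, kernel sizes and the hidden width are tunable.
#'
#' @param lookback_min Length `L` of the probability sequence (minutes) fed
#'   to the network. Default 60 (two feature windows of context).
#' @param filters Integer vector of length 3: filters per convolution layer.
#' @param kernels Integer vector of length 3: kernel sizes. With the default
#'   lookback the position counts work out to 60 -> 56 -> 28 -> 24 -> 12 ->
#'   10 -> global average.
#' @param fc_width Width of the first fully connected layer (the second is
#'   the single sigmoid output unit).
#' @param epochs Maximum training epochs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement) before training stops and the best weights are restored.
#' @param val_frac Fraction of pairs held out as the validation split.
#' @param train_stride_min Training pairs are taken every this many minutes;
#'   inference is always at 1-minute resolution.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(lookback_min = 60L,
                       filters = c(8L, 16L, 16L),
                       kernels = c(5L, 5L, 3L),
                       fc_width = 16L,
                       epochs = 30L,
                       lr = 2e-3,
                       batch_size = 256L,
                       patience = 5L,
                       val_frac = 0.1,
                       train_stride_min = 3L,
                       seed = 1L) {
  if (length(filters) != 3L || length(kernels) != 3L) {
    abort("the network has exactly 3 convolution layers: `filters` and `kernels` must have length 3")
  }
  p1 <- lookback_min - kernels[1] + 1L
  if (p1 %% 2L != 0L) abort("lookback and first kernel must leave an even position count for max pooling")
  p2 <- p1 %/% 2L - kernels[2] + 1L
  if (p2 %% 2L != 0L || p2 < 2L) abort("second convolution output must have an even, positive position count")
  p3 <- p2 %/% 2L - kernels[3] + 1L
  if (p3 < 1L) abort("third convolution kernel too large for the pooled sequence")
  structure(list(
    lookback_min = as.integer(lookback_min),
    filters = as.integer(filters), kernels = as.integer(kernels),
    fc_width = as.integer(fc_width), epochs = as.integer(epochs),
    lr = lr, batch_size = as.integer(batch_size),
    patience = as.integer(patience), val_frac = val_frac,
    train_stride_min = as.integer(train_stride_min),
    seed = as.integer(seed),
    positions = c(conv1 = p1, pool1 = p1 %/% 2L, conv2 = p2,
                  pool2 = p2 %/% 2L, conv3 = p3)
  ), class = "cnn_config")
}

#' Per-participant RNG stream seed
#'
#' Derives a stable 32-bit seed from a global seed and a participant id
#' (small-prime rolling hash of the id folded into the seed), so cohorts
#' are reproducible participant by participant.
#'
#' @param seed Integer global seed.
#' @param participant_id Participant identifier.
#' @return An integer seed below 2^31.
#' @export
participant_seed <- function(seed, participant_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(participant_id))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629) + 1L
}
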
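# End-to-end orchestration: GPS labeling -> featurization -> stage 1 ->
# out-of-fold minute series -> stage 2, and the cohort experiment used for
# validation on synthetic data.

#' GPS minute states for a participant
#'
#' Convenience wrapper: labels work intervals and rasterises them onto the
#' 05:45-24:00 minute grid of the requested days.
#'
#' @param gps GPS tibble of one participant.
#' @param workplaces Workplace coordinates (`lat`, `lon`).
#' @param dates Days to rasterise (default: all days with fixes).
#' @param cfg A [pipeline_config()].
#' @return Tibble `participant_id, date, minute, at_work`.
#' @export
gps_minute_states <- function(gps, workplaces, dates = NULL,
                              cfg = pipeline_config()) {
  if (is.null(dates)) dates <- sort(unique(local_date(gps$timestamp, cfg$tz)))
  iv <- label_work_intervals(gps, workplaces, cfg)
  minute_gps_state(iv, dates, participant_id = gps$participant_id[1], cfg = cfg)
}

#' Fit the two-stage work-mode model for one participant
#'
#' Runs the full training pipeline on one participant's streams: labels
#' GPS-defined work intervals, classifies days, builds the 1800-second
#' training windows from typical workdays, fits the stage-1 boosted-tree
#' classifier with day-blocked cross-validation, produces out-of-fold
#' per-minute provisional probabilities for the training days, and fits the
#' stage-2 temporal model on sequences of those probabilities.
#'
#' @param events,gps Event and GPS tibbles of one participant.
#' @param workplaces Workplace coordinates (`lat`, `lon`; 1-5 rows).
#' @param cfg A [pipeline_config()].
#' @param cnn A [cnn_config()].
#' @param seed Integer seed for fold assignment, imputation and both model
#'   fits.
#' @param train_dates Restrict training to these dates (default: all days
#'   with GPS fixes).
#' @return An object of class `workmode_fit`.
#' @export
fit_workmode <- function(events, gps, workplaces, cfg = pipeline_config(),
                         cnn = cnn_config(), seed = 1L, train_dates = NULL) {
  tz <- cfg$tz
  all_dates <- sort(unique(local_date(gps$timestamp, tz)))
  if (is.null(train_dates)) train_dates <- all_dates
  train_dates <- as.Date(intersect(train_dates, all_dates), origin = "1970-01-01")

  intervals <- label_work_intervals(gps, workplaces, cfg)
  minute_states <- minute_gps_state(intervals, train_dates,
                                    participant_id = gps$participant_id[1],
                                    cfg = cfg)
  days <- classify_days(intervals, minute_states, cfg)
  typical <- days$date[days$day_class == "typical"]
  if (length(typical) < cfg$min_typical_days) {
    abort(sprintf("participant has %d typical workday(s); at least %d are required",
                  length(typical), cfg$min_typical_days))
  }

  train <- build_training_set(events, minute_states, days, cfg)
  vocab <- attr(train, "vocab")
  stage1 <- train_stage1(train, k = 5L, seed = seed)

  # out-of-fold provisional minute series on the typical training days:
  # each day is scored by the booster that never saw it
  used_dates <- sort(unique(train$date))
  mfm <- minute_feature_matrix(events, used_dates, vocab, cfg)
  day_fold <- train |>
    distinct(.data$date) |>
    mutate(fold = stage1$fold[match(.data$date, train$date)])
  prov <- map(seq_len(nrow(day_fold)), function(i) {
    rows <- mfm[mfm$date == day_fold$date[i], ]
    p <- predict_proba(stage1, rows[stage1$feature_names], fold = day_fold$fold[i])
    tibble(participant_id = rows$participant_id, date = rows$date,
           minute = rows$minute, provisional = p)
  }) |> list_rbind()

  cnn$seed <- as.integer(seed + 11L)
  pairs <- make_sequences(prov, minute_states[minute_states$date %in% used_dates, ],
                          cnn$lookback_min)
  stage2 <- train_stage2(pairs, cnn)

  structure(list(
    participant_id = gps$participant_id[1],
    stage1 = stage1, stage2 = stage2, vocab = vocab,
    cfg = cfg, cnn = cnn, workplaces = as_tibble(workplaces),
    days = days, minute_states = minute_states,
    oof_provisional = prov,
    n_typical = length(typical), train_dates = train_dates,
    seed = as.integer(seed)
  ), class = "workmode_fit")
}

#' @export
print.workmode_fit <- function(x, ...) {
  cat(sprintf("<workmode_fit %s: %d apps, %d typical training days, stage-1 oof AUC %.3f>\n",
              x$participant_id, length(x$vocab), x$n_typical, x$stage1$oof_auc))
  invisible(x)
}

#' Predict the per-minute probability in work mode
#'
#' Applies a fitted two-stage model to (possibly new) days of a
#' participant: computes the sliding 1800-second feature windows ending at
#' every minute of the 05:45-24:00 grid, scores them with the refit stage-1
#' model, and smooths the resulting provisional series with the stage-2
#' network.
#'
#' @param fit A `workmode_fit`.
#' @param events Event tibble covering the requested days.
#' @param gps GPS tibble (used only to default `dates`).
#' @param dates Days to predict (default: all days with GPS fixes).
#' @return Tibble `participant_id, date, minute, provisional, final`.
#' @export
predict_workmode <- function(fit, events, gps = NULL, dates = NULL) {
  cfg <- fit$cfg
  if (is.null(dates)) {
    if (is.null(gps)) abort("supply `dates` or `gps`")
    dates <- sort(unique(local_date(gps$timestamp, cfg$tz)))
  }
  mfm <- minute_feature_matrix(events, dates, fit$vocab, cfg)
  prov <- tibble(participant_id = mfm$participant_id, date = mfm$date,
                 minute = mfm$minute,
                 provisional = predict_proba(fit$stage1,
                                             mfm[fit$stage1$feature_names]))
  predict_series(fit$stage2, prov)
}

#' Run the synthetic cohort experiment
#'
#' Simulates a cohort with known ground truth, fits the two-stage model per
#' participant on the first `n_days - holdout_days` days, predicts the
#' remaining held-out days and evaluates them: transition-masked AUC (final
#' and stage-1-only), per-day accuracy against the "9-to-5" reference, and
#' the four-state segmentation totals.
#'
#' @param n_participants,n_days Cohort size (profiles use seeds
#'   `1..n_participants`).
#' @param seed Global seed for streams and model fits.
#' @param holdout_days Days per participant reserved for evaluation.
#' @param sim A [sim_config()].
#' @param cfg A [pipeline_config()].
#' @param cnn A [cnn_config()].
#' @param verbose Print one line per participant.
#' @return A list with tibbles `participants` (per-participant AUCs and
#'   operating characteristics), `days` (per person-day accuracies),
#'   `day_summaries` (four-state daily totals on held-out days) and the
#'   list `cohort` of means, SDs and paired tests.
#' @export
run_cohort_experiment <- function(n_participants = 20L, n_days = 30L, seed = 1L,
                                  holdout_days = 9L, sim = sim_config(),
                                  cfg = pipeline_config(), cnn = cnn_config(),
                                  verbose = FALSE) {
  cohort <- simulate_cohort(n_participants, n_days, seed, sim)
  parts <- list(); day_rows <- list(); seg_rows <- list()
  for (i in seq_len(n_participants)) {
    events <- cohort$events[[i]]; gps <- cohort$gps[[i]]
    profile <- cohort$profile[[i]]
    dates <- sort(unique(local_date(gps$timestamp, cfg$tz)))
    train_dates <- head(dates, length(dates) - holdout_days)
    eval_dates <- tail(dates, holdout_days)

    fit <- fit_workmode(events, gps, profile$workplaces, cfg, cnn,
                        seed = participant_seed(seed, profile$participant_id),
                        train_dates = train_dates)
    prob <- predict_workmode(fit, events, dates = eval_dates)
    ms <- gps_minute_states(gps, profile$workplaces, eval_dates, cfg)
    iv <- label_work_intervals(gps, profile$workplaces, cfg)
    days <- classify_days(iv[iv$date %in% eval_dates, ], ms, cfg)

    pa <- evaluate_participant(prob, ms, cfg)
    parts[[i]] <- pa
    day_rows[[i]] <- evaluate_days(prob, ms, days, cfg)
    seg_rows[[i]] <- summarize_day(classify_minutes(prob, ms, cfg$prob_threshold))
    if (verbose) {
      message(sprintf("%s: stage-1 AUC %.3f -> final AUC %.3f",
                      profile$participant_id, pa$auc_stage1, pa$auc_final))
    }
  }
  participants <- list_rbind(parts)
  days <- list_rbind(day_rows)
  seg <- list_rbind(seg_rows)

  gain_test <- paired_t(participants$auc_final, participants$auc_stage1)
  acc_test <- paired_t(days$accuracy, days$reference_accuracy)
  list(
    participants = participants, days = days, day_summaries = seg,
    cohort = list(
      mean_auc_final = mean(participants$auc_final),
      sd_auc_final = sd(participants$auc_final),
      mean_auc_stage1 = mean(participants$auc_stage1),
      sd_auc_stage1 = sd(participants$auc_stage1),
      pct_auc_above_floor = 100 * mean(participants$auc_final > cfg$auc_floor),
      auc_gain_t = gain_test$t, auc_gain_df = gain_test$df,
      auc_gain_p_one_sided = if (gain_test$t > 0) gain_test$p / 2 else 1 - gain_test$p / 2,
      mean_accuracy = mean(days$accuracy, na.rm = TRUE),
      mean_reference_accuracy = mean(days$reference_accuracy),
      accuracy_vs_reference_t = acc_test$t,
      accuracy_vs_reference_p = acc_test$p
    )
  )
}
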
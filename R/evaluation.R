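# Evaluation protocol: per person-day accuracy with a transition exclusion,
# per-participant rank AUC, sensitivity/specificity at the 0.5 threshold, a
# fixed "9-to-5" reference predictor, paired t tests, and the
# stability-vs-training-days analysis.

#' Transition mask
#'
#' Minutes within `excl` minutes of a GPS on/off switch are excluded from
#' accuracy and ROC computations. The switch sits at the first minute of
#' the new state; that minute and the `excl` minutes on each side are
#' masked.
#'
#' @param gps Binary vector of per-minute GPS states (time ordered).
#' @param excl Minutes excluded on each side of a switch (default 15).
#' @return Logical vector: `TRUE` where the minute is kept.
#' @export
transition_mask <- function(gps, excl = 15L) {
  n <- length(gps)
  keep <- rep(TRUE, n)
  if (n < 2) return(keep)
  switches <- which(gps[-1] != gps[-n]) + 1L
  for (s in switches) {
    keep[max(1L, s - excl):min(n, s + excl)] <- FALSE
  }
  keep
}

#' Per-day accuracy against GPS labels
#'
#' Fraction of unmasked minutes where the thresholded probability agrees
#' with the GPS-defined state.
#'
#' @param probs Per-minute probabilities.
#' @param gps Binary GPS states, same length.
#' @param mask Logical keep-mask (default: keep all).
#' @param threshold Work-mode threshold (default 0.5).
#' @export
day_accuracy <- function(probs, gps, mask = NULL, threshold = 0.5) {
  stopifnot(length(probs) == length(gps))
  if (is.null(mask)) mask <- rep(TRUE, length(gps))
  if (!any(mask)) abort("no unmasked minute to score")
  mean((probs[mask] > threshold) == (gps[mask] == 1))
}

# rank-based AUC (ties get half credit); NA when one class is absent
auc_rank <- function(scores, labels) {
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- as.integer(labels[ok] == 1)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-participant AUC
#'
#' Rank-based area under the ROC curve of the work-mode probabilities
#' against GPS-defined states over all unmasked minutes. Days with only one
#' class (e.g. holidays alone) yield no AUC: `NA` is returned when a class
#' is absent after masking.
#'
#' @inheritParams day_accuracy
#' @param labels Binary GPS states.
#' @export
participant_auc <- function(probs, labels, mask = NULL) {
  stopifnot(length(probs) == length(labels))
  if (is.null(mask)) mask <- rep(TRUE, length(labels))
  auc_rank(probs[mask], labels[mask])
}

#' "9-to-5" reference accuracy
#'
#' Accuracy of the fixed baseline that declares every day to be worked
#' from 09:00 to 17:00, evaluated over all minutes of the 05:45-24:00 span
#' (the baseline uses no transition mask).
#'
#' @param gps Binary GPS states on the minute grid.
#' @param minute Minute-of-day of each entry (defaults to the standard
#'   grid).
#' @export
reference_accuracy_9to5 <- function(gps, minute = .GRID_MIN) {
  stopifnot(length(gps) == length(minute))
  pred <- minute >= 540L & minute < 1020L
  mean(pred == (gps == 1))
}

#' Sensitivity and specificity at a threshold
#'
#' True positives are minutes called on-working by both the probability and
#' GPS. Undefined ratios (no positives or no negatives among unmasked
#' minutes) are returned as `NA`.
#'
#' @inheritParams day_accuracy
#' @return Named numeric vector `c(sensitivity =, specificity =)`.
#' @export
sensitivity_specificity <- function(probs, gps, mask = NULL, threshold = 0.5) {
  stopifnot(length(probs) == length(gps))
  if (is.null(mask)) mask <- rep(TRUE, length(gps))
  p <- probs[mask] > threshold; g <- gps[mask] == 1
  tp <- sum(p & g); fn <- sum(!p & g)
  tn <- sum(!p & !g); fp <- sum(p & !g)
  c(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Paired t test (closed form)
#'
#' Two-sided paired t test on per-day values. If all differences are
#' exactly zero the statistic is 0 with p = 1; a nonzero constant
#' difference (zero variance) is an error.
#'
#' @param a,b Equal-length numeric vectors of paired values.
#' @return A list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length")
  d <- a - b
  n <- length(d)
  if (n < 2) abort("need at least 2 pairs")
  if (all(d == 0)) return(list(t = 0, p = 1, df = n - 1, mean_diff = 0))
  s <- sd(d)
  if (s == 0) abort("differences have zero variance")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), df = n - 1, mean_diff = mean(d))
}

#' Per-day evaluation table
#'
#' Computes, for every person-day, the transition-masked accuracy of the
#' final probabilities, the unmasked "9-to-5" reference accuracy and the
#' day class.
#'
#' @param prob Probability tibble `participant_id, date, minute, final`.
#' @param gps_states Minute tibble from [minute_gps_state()].
#' @param days Day-class tibble from [classify_days()].
#' @param cfg A [pipeline_config()].
#' @return Tibble `participant_id, date, day_class, accuracy,
#'   reference_accuracy, n_minutes`.
#' @export
evaluate_days <- function(prob, gps_states, days, cfg = pipeline_config()) {
  d <- inner_join(prob, gps_states, by = c("participant_id", "date", "minute")) |>
    arrange(.data$participant_id, .data$date, .data$minute)
  d |>
    group_by(.data$participant_id, .data$date) |>
    summarise(
      accuracy = {
        m <- transition_mask(.data$at_work, cfg$transition_exclusion_min)
        if (any(m)) day_accuracy(.data$final, .data$at_work, m,
                                 cfg$prob_threshold) else NA_real_
      },
      reference_accuracy = reference_accuracy_9to5(.data$at_work, .data$minute),
      n_minutes = n(), .groups = "drop"
    ) |>
    left_join(days[c("participant_id", "date", "day_class")],
              by = c("participant_id", "date"))
}

#' Per-participant evaluation
#'
#' Pools all evaluated minutes of a participant, applies the transition
#' mask per day, and computes the final and stage-1 AUCs, sensitivity and
#' specificity at the configured threshold.
#'
#' @inheritParams evaluate_days
#' @return One-row tibble `participant_id, auc_final, auc_stage1,
#'   sensitivity, specificity, n_days, n_minutes`.
#' @export
evaluate_participant <- function(prob, gps_states, cfg = pipeline_config()) {
  d <- inner_join(prob, gps_states, by = c("participant_id", "date", "minute")) |>
    arrange(.data$participant_id, .data$date, .data$minute)
  masked <- d |>
    group_by(.data$participant_id, .data$date) |>
    mutate(keep = transition_mask(.data$at_work, cfg$transition_exclusion_min)) |>
    ungroup() |>
    filter(.data$keep)
  ss <- sensitivity_specificity(masked$final, masked$at_work,
                                threshold = cfg$prob_threshold)
  tibble(
    participant_id = d$participant_id[1],
    auc_final = auc_rank(masked$final, masked$at_work),
    auc_stage1 = if ("provisional" %in% names(masked)) {
      auc_rank(masked$provisional, masked$at_work)
    } else NA_real_,
    sensitivity = ss[["sensitivity"]], specificity = ss[["specificity"]],
    n_days = dplyr::n_distinct(d$date), n_minutes = nrow(masked)
  )
}

#' Stability of the AUC versus training days
#'
#' Refits the full two-stage model on growing prefixes of a participant's
#' days and evaluates each fit on the same fixed held-out days.
#'
#' @param events,gps Event and GPS tibbles of one participant.
#' @param workplaces Workplace coordinates (`lat`, `lon`).
#' @param day_counts Integer vector of training-set sizes (days, each at
#'   least the configured minimum of typical days).
#' @param eval_dates Held-out dates used for every count.
#' @param cfg,cnn Pipeline and network configuration.
#' @param seed Integer seed.
#' @return Tibble `n_days, n_typical, auc`.
#' @export
stability_curve <- function(events, gps, workplaces, day_counts, eval_dates,
                            cfg = pipeline_config(), cnn = cnn_config(),
                            seed = 1L) {
  all_dates <- sort(unique(local_date(gps$timestamp, cfg$tz)))
  train_pool <- setdiff(all_dates, eval_dates)
  train_pool <- as.Date(train_pool, origin = "1970-01-01")
  if (max(day_counts) > length(train_pool)) {
    abort("not enough training days for the requested counts")
  }
  eval_states <- gps_minute_states(gps, workplaces, eval_dates, cfg)
  rows <- map(sort(day_counts), function(nd) {
    fit <- fit_workmode(events, gps, workplaces, cfg, cnn, seed = seed,
                        train_dates = train_pool[seq_len(nd)])
    pr <- predict_workmode(fit, events, gps, dates = eval_dates)
    ev <- evaluate_participant(pr, eval_states, cfg)
    tibble(n_days = nd, n_typical = fit$n_typical, auc = ev$auc_final)
  })
  list_rbind(rows)
}
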
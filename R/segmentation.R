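# Four-state interpretation of a day: the final probability crossed with the
# GPS-defined location state.
#   office        p > threshold  and at the worksite
#   break_at_work p <= threshold and at the worksite
#   remote        p > threshold  and off-site
#   off           p <= threshold and off-site
# A probability of exactly the threshold falls on the non-working side.

#' Classify minutes into the four work-mode states
#'
#' @param prob Probability series tibble `participant_id, date, minute,
#'   final` (a `provisional` column is carried through if present).
#' @param gps_states Minute tibble from [minute_gps_state()].
#' @param threshold Work-mode probability threshold (default 0.5).
#' @return Tibble `participant_id, date, minute, final, at_work, state,
#'   episode` where `episode` numbers contiguous same-state runs within a
#'   day.
#' @export
classify_minutes <- function(prob, gps_states, threshold = 0.5) {
  d <- inner_join(prob, gps_states, by = c("participant_id", "date", "minute"))
  if (nrow(d) != nrow(prob) || nrow(d) != nrow(gps_states)) {
    abort("probability and GPS minute grids are misaligned")
  }
  d |>
    arrange(.data$participant_id, .data$date, .data$minute) |>
    mutate(state = dplyr::case_when(
      .data$final > threshold & .data$at_work == 1L ~ "office",
      .data$final <= threshold & .data$at_work == 1L ~ "break_at_work",
      .data$final > threshold ~ "remote",
      TRUE ~ "off"
    )) |>
    group_by(.data$participant_id, .data$date) |>
    mutate(episode = cumsum(.data$state != dplyr::lag(.data$state,
                                                      default = "<none>"))) |>
    ungroup()
}

#' List contiguous state episodes
#'
#' @param seg Output of [classify_minutes()].
#' @return Tibble `participant_id, date, episode, state, start_minute,
#'   end_minute, minutes` (end exclusive).
#' @export
segmentation_episodes <- function(seg) {
  seg |>
    group_by(.data$participant_id, .data$date, .data$episode, .data$state) |>
    summarise(start_minute = min(.data$minute),
              end_minute = max(.data$minute) + 1L,
              minutes = n(), .groups = "drop")
}

#' Daily totals of the four states
#'
#' Aggregates a segmentation to hours per state and the two work-hour
#' definitions: probability-defined work hours (office + remote) and
#' GPS-defined work hours (office + break).
#'
#' @param seg Output of [classify_minutes()].
#' @return Tibble `participant_id, date, office_h, break_h, off_h,
#'   remote_h, prob_work_h, gps_work_h`.
#' @export
summarize_day <- function(seg) {
  seg |>
    group_by(.data$participant_id, .data$date) |>
    summarise(
      office_h = sum(.data$state == "office") / 60,
      break_h = sum(.data$state == "break_at_work") / 60,
      off_h = sum(.data$state == "off") / 60,
      remote_h = sum(.data$state == "remote") / 60,
      .groups = "drop"
    ) |>
    mutate(prob_work_h = .data$office_h + .data$remote_h,
           gps_work_h = .data$office_h + .data$break_h)
}
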
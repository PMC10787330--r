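# ggplot2 views of the pipeline's result types.

minute_to_hm <- function(m) sprintf("%02d:%02d", m %/% 60, m %% 60)

#' Probability-in-work-mode diagram for one day
#'
#' Scatter of the final per-minute probability, coloured by the GPS-defined
#' state, with the decision threshold drawn — the standard one-day diagram
#' for reading off office, break, off and remote-working periods.
#'
#' @param prob Probability tibble (`date, minute, final`).
#' @param gps_states Minute tibble from [minute_gps_state()].
#' @param date Day to plot (default: first available).
#' @param threshold Work-mode threshold.
#' @return A ggplot object.
#' @export
plot_day_probability <- function(prob, gps_states, date = NULL, threshold = 0.5) {
  if (is.null(date)) date <- min(prob$date)
  d <- inner_join(prob[prob$date == date, ], gps_states[gps_states$date == date, ],
                  by = c("participant_id", "date", "minute"))
  d$gps <- factor(ifelse(d$at_work == 1, "at work", "off work"),
                  levels = c("at work", "off work"))
  brk <- seq(360, 1440, by = 180)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$minute, y = .data$final,
                                  colour = .data$gps)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::scale_colour_manual(values = c("at work" = "#c0392b",
                                            "off work" = "#2980b9")) +
    ggplot2::scale_x_continuous(breaks = brk, labels = minute_to_hm(brk)) +
    ggplot2::labs(x = NULL, y = "probability in work mode",
                  colour = "GPS", title = format(date)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Four-state segmentation ribbon for one day
#'
#' @param seg Output of [classify_minutes()].
#' @param date Day to plot (default: first available).
#' @return A ggplot object.
#' @export
plot_segmentation <- function(seg, date = NULL) {
  if (is.null(date)) date <- min(seg$date)
  ep <- segmentation_episodes(seg[seg$date == date, ])
  pal <- c(office = "#c0392b", break_at_work = "#f39c12",
           off = "#2980b9", remote = "#8e44ad")
  brk <- seq(360, 1440, by = 180)
  ggplot2::ggplot(ep) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_minute,
                                    xmax = .data$end_minute,
                                    ymin = 0, ymax = 1, fill = .data$state)) +
    ggplot2::scale_fill_manual(values = pal) +
    ggplot2::scale_x_continuous(breaks = brk, labels = minute_to_hm(brk)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "state", title = format(date)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' AUC versus number of training days
#'
#' @param stability Tibble from [stability_curve()].
#' @return A ggplot object.
#' @export
plot_stability <- function(stability) {
  ggplot2::ggplot(stability, ggplot2::aes(x = .data$n_days, y = .data$auc)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training days", y = "held-out AUC") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Feature importance of a stage-1 model
#' @param object A `stage1_model`.
#' @param top_n Number of features shown.
#' @param ... Unused.
#' @method autoplot stage1_model
#' @export
autoplot.stage1_model <- function(object, top_n = 20L, ...) {
  imp <- head(object$importance, top_n)
  ggplot2::ggplot(imp, ggplot2::aes(x = stats::reorder(.data$feature, .data$gain),
                                    y = .data$gain)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "gain") +
    ggplot2::theme_minimal()
}

#' Training curves of a stage-2 model
#' @param object A `stage2_model`.
#' @param ... Unused.
#' @method autoplot stage2_model
#' @export
autoplot.stage2_model <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                           names_to = "split", values_to = "loss")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 3) +
    ggplot2::labs(x = "epoch", y = "binary cross-entropy") +
    ggplot2::theme_minimal()
}
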
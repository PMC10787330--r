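# Stage 2: the temporal model. The provisional per-minute probabilities from
# stage 1 are smoothed by the 1-D convolutional network: the probability of
# minute t is predicted from the L preceding provisional probabilities of
# the same day.

#' Build training pairs from a provisional probability series
#'
#' For every minute `t` with at least `L` preceding minutes on the same
#' day, forms the pair (input = provisional probabilities of `[t-L, t)`,
#' target = GPS-defined state at `t`). Sequences never cross midnight.
#'
#' @param provisional Tibble `participant_id, date, minute, provisional`
#'   on the contiguous 05:45-24:00 minute grid.
#' @param gps_states Tibble `participant_id, date, minute, at_work` on the
#'   same grid.
#' @param L Lookback length in minutes.
#' @return A list with matrix `X` (one row per pair, `L` columns), vector
#'   `y`, and tibble `meta` (`participant_id, date, minute` of the target).
#' @export
make_sequences <- function(provisional, gps_states, L) {
  d <- inner_join(provisional, gps_states,
                  by = c("participant_id", "date", "minute")) |>
    arrange(.data$participant_id, .data$date, .data$minute)
  days <- split(d, list(d$participant_id, d$date), drop = TRUE)
  Xs <- list(); ys <- list(); metas <- list()
  for (g in days) {
    n <- nrow(g)
    if (any(diff(g$minute) != 1)) abort("minute grid must be contiguous within a day")
    if (L > n) abort(sprintf("lookback L = %d exceeds the day span (%d minutes)", L, n))
    if (L == n) next
    t_idx <- (L + 1L):n
    rows <- outer(t_idx - L, 0:(L - 1L), "+")
    Xs[[length(Xs) + 1L]] <- matrix(g$provisional[rows], nrow = length(t_idx))
    ys[[length(ys) + 1L]] <- g$at_work[t_idx]
    metas[[length(metas) + 1L]] <- g[t_idx, c("participant_id", "date", "minute")]
  }
  if (!length(Xs)) {
    return(list(X = matrix(numeric(), 0, L), y = numeric(),
                meta = tibble(participant_id = character(),
                              date = as.Date(character()), minute = integer())))
  }
  list(X = do.call(rbind, Xs), y = unlist(ys), meta = list_rbind(metas))
}

#' Train the stage-2 temporal model
#'
#' Fits the convolutional sequence model on training pairs (normally built
#' from out-of-fold stage-1 probabilities to avoid leakage). Training pairs
#' are subsampled at `config$train_stride_min` minutes; inference stays at
#' 1-minute resolution. Optimised with Adam on binary cross-entropy, with
#' early stopping on a held-out validation split and restoration of the
#' best weights.
#'
#' @param pairs Output of [make_sequences()], or a list with `X` and `y`.
#' @param config A [cnn_config()]; its `lookback_min` must match `ncol(X)`.
#' @return An object of class `stage2_model`.
#' @export
train_stage2 <- function(pairs, config = cnn_config()) {
  X <- pairs$X; y <- pairs$y
  if (ncol(X) != config$lookback_min) {
    abort(sprintf("pairs have lookback %d but config expects %d",
                  ncol(X), config$lookback_min))
  }
  if (!is.null(pairs$meta) && nrow(pairs$meta) == nrow(X) &&
      config$train_stride_min > 1L) {
    keep <- (pairs$meta$minute - .NIGHT_END_MIN) %% config$train_stride_min == 0L
    X <- X[keep, , drop = FALSE]; y <- y[keep]
  }
  if (length(unique(y)) < 2) {
    abort("stage-2 training needs pairs from both classes")
  }
  fit <- cnn_train(X, y, config)
  structure(list(
    weights = fit$weights, config = config, history = fit$history,
    best_epoch = fit$best_epoch, val_loss = fit$val_loss,
    n_pairs = nrow(X)
  ), class = "stage2_model")
}

#' Layer summary of a stage-2 model
#'
#' @param object A `stage2_model` (or a [cnn_config()]).
#' @param ... Unused.
#' @return Tibble with one row per layer: type, output shape, activation,
#'   pooling and parameter count.
#' @export
summary.stage2_model <- function(object, ...) {
  cfg <- if (inherits(object, "cnn_config")) object else object$config
  dm <- cnn_dims(cfg)
  Fl <- cfg$filters; K <- cfg$kernels
  tibble(
    layer = c("conv1", "conv2", "conv3", "fc1", "fc2"),
    type = c("conv", "conv", "conv", "fully_connected", "fully_connected"),
    output = c(sprintf("%d x %d", dm$P1, Fl[1]), sprintf("%d x %d", dm$P2, Fl[2]),
               sprintf("%d x %d", dm$P3, Fl[3]), sprintf("%d", cfg$fc_width), "1"),
    activation = c("relu", "relu", "relu", "relu", "sigmoid"),
    pooling = c("max", "max", "global_average", "", ""),
    n_params = c(K[1] * Fl[1] + Fl[1], K[2] * Fl[1] * Fl[2] + Fl[2],
                 K[3] * Fl[2] * Fl[3] + Fl[3],
                 Fl[3] * cfg$fc_width + cfg$fc_width, cfg$fc_width + 1)
  )
}

#' @export
print.stage2_model <- function(x, ...) {
  s <- summary(x)
  cat(sprintf("<stage2_model: %d conv + %d fc layers, %d params, trained %d pairs, best epoch %d (val loss %.4f)>\n",
              sum(s$type == "conv"), sum(s$type == "fully_connected"),
              sum(s$n_params), x$n_pairs, x$best_epoch, x$val_loss))
  invisible(x)
}

#' Smooth a provisional series into final probabilities
#'
#' Applies the stage-2 model to every minute of each day. The first `L`
#' minutes of a day have no full lookback window and carry the provisional
#' value through unchanged (the warm-up rule); all later minutes get the
#' network output. Deterministic; sequences never cross midnight.
#'
#' @param model A `stage2_model`.
#' @param provisional Tibble `participant_id, date, minute, provisional` on
#'   the contiguous minute grid.
#' @return The input tibble with a `final` column appended.
#' @export
predict_series <- function(model, provisional) {
  stopifnot(inherits(model, "stage2_model"))
  cfg <- model$config
  L <- cfg$lookback_min
  out <- provisional |>
    arrange(.data$participant_id, .data$date, .data$minute)
  days <- split(seq_len(nrow(out)), list(out$participant_id, out$date), drop = TRUE)
  final <- rep(NA_real_, nrow(out))
  for (idx in days) {
    v <- out$provisional[idx]
    n <- length(v)
    if (any(diff(out$minute[idx]) != 1)) {
      abort("minute grid must be contiguous within a day")
    }
    if (n < L) abort(sprintf("day span (%d) shorter than lookback (%d)", n, L))
    f <- v
    if (n > L) {
      t_idx <- (L + 1L):n
      rows <- outer(t_idx - L, 0:(L - 1L), "+")
      X <- matrix(v[rows], nrow = length(t_idx))
      f[t_idx] <- cnn_predict_mat(model$weights, X, cfg)
    }
    final[idx] <- f
  }
  out$final <- final
  out
}
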
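# broom-style accessors for the fitted objects.

#' Tidy a stage-1 model
#'
#' @param x A `stage1_model`.
#' @param ... Unused.
#' @return Feature-importance tibble `feature, gain, rank`.
#' @method tidy stage1_model
#' @export
tidy.stage1_model <- function(x, ...) {
  mutate(x$importance, rank = row_number())
}

#' @rdname tidy.stage1_model
#' @return For `glance()`: one-row tibble with the out-of-fold AUC, fold
#'   count, boosting rounds of the refit model and training size.
#' @method glance stage1_model
#' @export
glance.stage1_model <- function(x, ...) {
  tibble(oof_auc = x$oof_auc, k_folds = x$k, nrounds = x$final_rounds,
         n_features = length(x$feature_names), n_rows = nrow(x$oof))
}

#' Tidy a stage-2 model
#'
#' @param x A `stage2_model`.
#' @param ... Unused.
#' @return Per-epoch loss tibble `epoch, train_loss, val_loss`.
#' @method tidy stage2_model
#' @export
tidy.stage2_model <- function(x, ...) x$history

#' @rdname tidy.stage2_model
#' @method glance stage2_model
#' @export
glance.stage2_model <- function(x, ...) {
  s <- summary(x)
  tibble(best_epoch = x$best_epoch, val_loss = x$val_loss,
         n_pairs = x$n_pairs, n_params = sum(s$n_params),
         lookback_min = x$config$lookback_min)
}

#' Tidy a fitted participant pipeline
#'
#' @param x A `workmode_fit`.
#' @param ... Unused.
#' @return The stage-1 importance table.
#' @method tidy workmode_fit
#' @export
tidy.workmode_fit <- function(x, ...) tidy(x$stage1)

#' @rdname tidy.workmode_fit
#' @method glance workmode_fit
#' @export
glance.workmode_fit <- function(x, ...) {
  tibble(participant_id = x$participant_id,
         n_typical_days = x$n_typical,
         n_apps = length(x$vocab),
         stage1_oof_auc = x$stage1$oof_auc,
         stage2_val_loss = x$stage2$val_loss)
}
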
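# Stage 1: per-participant gradient-boosted trees mapping window features to
# a provisional work-mode probability (two-class probability output).

feature_columns <- function(data) {
  setdiff(names(data), c("participant_id", "date", "window_start",
                         "minute", "label"))
}

# day-blocked, label-balanced fold assignment: days ordered by their share
# of positive windows, snake-dealt over folds
assign_day_folds <- function(data, k) {
  day_stats <- data |>
    group_by(.data$date) |>
    summarise(pos = mean(.data$label), .groups = "drop") |>
    arrange(.data$pos)
  n <- nrow(day_stats)
  cycle <- c(seq_len(k), rev(seq_len(k)))
  day_stats$fold <- rep_len(cycle, n)
  setNames(day_stats$fold, as.character(day_stats$date))
}

xgb_fit <- function(X, y, params, nrounds, evals = NULL, early = NULL) {
  dtr <- xgboost::xgb.DMatrix(X, label = y)
  ev <- if (!is.null(evals)) {
    list(val = xgboost::xgb.DMatrix(evals$X, label = evals$y))
  } else list()
  xgboost::xgb.train(
    params = xgboost::xgb.params(
      objective = "binary:logistic", max_depth = params$max_depth,
      learning_rate = params$learning_rate, nthread = 1L,
      seed = params$seed
    ),
    data = dtr, nrounds = nrounds, evals = ev,
    early_stopping_rounds = early, verbose = 0
  )
}

#' Train the stage-1 classifier
#'
#' Fits gradient-boosted trees per participant with k-fold cross-validation.
#' Folds are blocked by day (all windows of a day share a fold) and balanced
#' by label prevalence; when the data carry no `date` column, plain
#' label-stratified row folds are used instead. Every training row receives
#' an out-of-fold probability from the model trained on the other folds;
#' missing values are imputed by resampling within the training folds only.
#' The final model is refit on all rows with the median of the fold-optimal
#' boosting rounds.
#'
#' @param data Tibble with a 0/1 `label` column, optional `date`,
#'   `participant_id`, `window_start`/`minute` metadata, and numeric feature
#'   columns (everything else).
#' @param k Number of folds (default 5).
#' @param seed Integer seed controlling fold assignment, imputation and
#'   boosting.
#' @param max_depth,learning_rate,nrounds,early_stopping_rounds Boosting
#'   hyperparameters (unreported upstream; these are package defaults).
#' @return An object of class `stage1_model`: the refit booster (raw
#'   serialised), fold boosters, out-of-fold probabilities, gain-based
#'   feature importance, the imputation reference and metadata.
#' @export
train_stage1 <- function(data, k = 5L, seed = 1L,
                         max_depth = 4L, learning_rate = 0.1,
                         nrounds = 400L, early_stopping_rounds = 20L) {
  if (!"label" %in% names(data)) abort("`data` needs a 0/1 `label` column")
  y <- as.numeric(data$label)
  if (length(unique(y)) < 2) abort("both classes must be present in the training data")
  if (min(table(y)) < k) abort(sprintf("need at least k = %d rows per class", k))
  feats <- feature_columns(data)
  if (!length(feats)) abort("no feature columns found")

  params <- list(max_depth = max_depth, learning_rate = learning_rate,
                 seed = as.integer(seed))
  has_dates <- "date" %in% names(data)
  if (has_dates) {
    k_eff <- min(k, length(unique(data$date)))
    if (k_eff < 2) abort("need at least 2 distinct days for day-blocked folds")
    day_fold <- assign_day_folds(data, k_eff)
    fold <- unname(day_fold[as.character(data$date)])
  } else {
    k_eff <- k
    fold <- local_rng(seed, {
      f <- integer(length(y))
      for (cls in unique(y)) {
        idx <- which(y == cls)
        f[idx] <- sample(rep_len(seq_len(k_eff), length(idx)))
      }
      f
    })
  }
  for (f in seq_len(k_eff)) {
    if (length(unique(y[fold != f])) < 2) {
      abort("a class is absent from the training part of a fold; use fewer folds")
    }
  }

  Xall <- as.matrix(data[feats])
  oof <- rep(NA_real_, length(y))
  fold_models <- vector("list", k_eff)
  best_iters <- integer(k_eff)
  for (f in seq_len(k_eff)) {
    tr <- fold != f; va <- !tr
    ref <- impute_reference(as.data.frame(Xall[tr, , drop = FALSE]))
    Xtr <- as.matrix(impute_missing(as.data.frame(Xall[tr, , drop = FALSE]),
                                    ref, seed = seed + f))
    Xva <- as.matrix(impute_missing(as.data.frame(Xall[va, , drop = FALSE]),
                                    ref, seed = seed + 100L + f))
    m <- xgb_fit(Xtr, y[tr], params, nrounds,
                 evals = list(X = Xva, y = y[va]), early = early_stopping_rounds)
    bi <- xgboost::xgb.attr(m, "best_iteration")
    best_iters[f] <- if (is.null(bi) || !length(bi)) nrounds else as.integer(bi)
    oof[va] <- predict(m, xgboost::xgb.DMatrix(Xva),
                       iterationrange = c(1, best_iters[f]))
    fold_models[[f]] <- list(raw = xgboost::xgb.save.raw(m), ref = ref,
                             best_iter = best_iters[f])
  }

  ref_all <- impute_reference(as.data.frame(Xall))
  X_imp <- as.matrix(impute_missing(as.data.frame(Xall), ref_all, seed = seed))
  final_rounds <- max(10L, as.integer(round(median(best_iters))))
  final <- xgb_fit(X_imp, y, params, final_rounds)

  imp <- tryCatch(xgboost::xgb.importance(model = final), error = function(e) NULL)
  importance <- tibble(feature = feats, gain = 0)
  if (!is.null(imp) && nrow(imp)) {
    idx <- match(imp$Feature, paste0("f", seq_along(feats) - 1L))
    idx[is.na(idx)] <- match(imp$Feature[is.na(idx)], feats)
    ok <- !is.na(idx)
    importance$gain[idx[ok]] <- imp$Gain[ok]
  }
  importance <- arrange(importance, dplyr::desc(.data$gain))

  structure(list(
    booster_raw = xgboost::xgb.save.raw(final),
    fold_models = fold_models,
    fold = fold, k = k_eff,
    feature_names = feats,
    impute_ref = ref_all,
    oof = tibble(row = seq_along(y), label = y, prob = oof,
                 date = if (has_dates) data$date else as.Date(NA)),
    oof_auc = auc_rank(oof, y),
    importance = importance,
    best_iters = best_iters, final_rounds = final_rounds,
    params = params, seed = as.integer(seed)
  ), class = "stage1_model")
}

booster_of <- function(raw) xgboost::xgb.load.raw(raw)

#' Predict provisional probabilities
#'
#' Applies a fitted stage-1 model to new feature rows. Missing values are
#' imputed from the model's training reference; predictions are
#' deterministic and lie in `[0, 1]`.
#'
#' @param model A `stage1_model`.
#' @param newdata Data frame containing the model's feature columns, or a
#'   numeric matrix with matching column count.
#' @param fold Optional fold number: use that fold's booster (trained
#'   without the fold's days) instead of the refit model — this is how
#'   out-of-fold minute series are produced for stage-2 training.
#' @return Numeric vector of probabilities.
#' @export
predict_proba <- function(model, newdata, fold = NULL) {
  stopifnot(inherits(model, "stage1_model"))
  nd <- as.data.frame(newdata)
  missing_cols <- setdiff(model$feature_names, names(nd))
  if (is.matrix(newdata) && is.null(colnames(newdata)) &&
      ncol(newdata) == length(model$feature_names)) {
    nd <- as.data.frame(newdata); names(nd) <- model$feature_names
    missing_cols <- character()
  }
  if (length(missing_cols)) {
    abort(sprintf("newdata lacks feature column(s): %s",
                  paste(head(missing_cols, 5), collapse = ", ")))
  }
  nd <- nd[model$feature_names]
  if (is.null(fold)) {
    ref <- model$impute_ref; raw <- model$booster_raw; itr <- NULL
  } else {
    fm <- model$fold_models[[fold]]
    ref <- fm$ref; raw <- fm$raw; itr <- c(1, fm$best_iter)
  }
  X <- as.matrix(impute_missing(nd, ref, seed = model$seed + 7L))
  predict(booster_of(raw), xgboost::xgb.DMatrix(X), iterationrange = itr)
}

#' Greedy minimal-feature search
#'
#' Ranks features by the full model's gain importance and adds them one by
#' one, retraining the cross-validated model on each subset, until the
#' out-of-fold AUC of the subset comes within `delta` of the full-feature
#' AUC.
#'
#' @inheritParams train_stage1
#' @param delta Tolerated AUC loss (must be positive; default 0.01).
#' @return A list with `features` (the selected subset, in importance
#'   order), `trace` (tibble `n_features, feature_added, auc`) and
#'   `auc_full`.
#' @export
greedy_minimal_features <- function(data, delta = 0.01, seed = 1L, k = 5L, ...) {
  if (delta <= 0) abort("`delta` must be positive")
  full <- train_stage1(data, k = k, seed = seed, ...)
  ranked <- full$importance$feature
  meta <- intersect(names(data), c("participant_id", "date", "window_start", "label"))
  trace <- list()
  for (j in seq_along(ranked)) {
    sub <- data[c(meta, ranked[seq_len(j)])]
    m <- train_stage1(sub, k = k, seed = seed, ...)
    trace[[j]] <- tibble(n_features = j, feature_added = ranked[j],
                         auc = m$oof_auc)
    if (full$oof_auc - m$oof_auc < delta) break
  }
  trace <- list_rbind(trace)
  list(features = ranked[seq_len(nrow(trace))], trace = trace,
       auc_full = full$oof_auc)
}

#' @export
print.stage1_model <- function(x, ...) {
  cat(sprintf("<stage1_model: %d features, %d-fold day-blocked CV, oof AUC %.3f>\n",
              length(x$feature_names), x$k, x$oof_auc))
  invisible(x)
}
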
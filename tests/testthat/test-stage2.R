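# helpers to build aligned minute series over several synthetic days
series_of <- function(values_by_day, pid = "T01") {
  out <- list()
  for (i in seq_along(values_by_day)) {
    out[[i]] <- tibble::tibble(
      participant_id = pid, date = as.Date("2022-03-01") + i - 1,
      minute = 345:1439, provisional = values_by_day[[i]]
    )
  }
  dplyr::bind_rows(out)
}

states_of <- function(labels_by_day, pid = "T01") {
  out <- list()
  for (i in seq_along(labels_by_day)) {
    out[[i]] <- tibble::tibble(
      participant_id = pid, date = as.Date("2022-03-01") + i - 1,
      minute = 345:1439, at_work = as.integer(labels_by_day[[i]])
    )
  }
  dplyr::bind_rows(out)
}

# blocky day: work 09:00-17:00
blocky <- function() as.integer(345:1439 >= 540 & 345:1439 < 1020)

test_that("sequence construction slices the provisional series exactly", {
  n <- 100L
  prov <- tibble::tibble(participant_id = "T01", date = as.Date("2022-03-01"),
                         minute = seq(345L, by = 1L, length.out = n),
                         provisional = seq_len(n) / n)
  gps <- tibble::tibble(participant_id = "T01", date = as.Date("2022-03-01"),
                        minute = prov$minute, at_work = rep(0:1, length.out = n))
  pr <- make_sequences(prov, gps, L = 10L)
  expect_equal(nrow(pr$X), 90)
  expect_equal(pr$X[1, ], prov$provisional[1:10])        # exact slices
  expect_equal(pr$X[90, ], prov$provisional[90:99])
  expect_equal(pr$y, gps$at_work[11:100])
  expect_equal(pr$meta$minute, prov$minute[11:100])

  expect_equal(nrow(make_sequences(prov, gps, L = 100L)$X), 0)
  expect_error(make_sequences(prov, gps, L = 101L), "exceeds the day span")
})

test_that("the network structure is three conv and two fully connected layers", {
  cfg <- tiny_cnn()
  s <- summary.stage2_model(cfg)
  expect_equal(sum(s$type == "conv"), 3)
  expect_equal(sum(s$type == "fully_connected"), 2)
  expect_equal(s$pooling[1:3], c("max", "max", "global_average"))
  expect_equal(s$activation, c("relu", "relu", "relu", "relu", "sigmoid"))
  # also for the default configuration
  s2 <- summary.stage2_model(cnn_config())
  expect_equal(sum(s2$type == "conv"), 3)
  expect_equal(sum(s2$type == "fully_connected"), 2)
})

test_that("backpropagation matches numerical gradients", {
  cfg <- tiny_cnn()
  set.seed(4)
  X <- matrix(runif(8 * cfg$lookback_min), 8)
  y <- rbinom(8, 1, 0.5)
  W <- workmode:::cnn_init(cfg)
  ix <- workmode:::cnn_idx(nrow(X), cfg)
  cache <- workmode:::cnn_forward(W, X, cfg, ix, keep = TRUE)
  g <- workmode:::cnn_backward(W, cache, y, cfg, ix)
  loss_at <- function(W) workmode:::bce(workmode:::cnn_forward(W, X, cfg, ix), y)
  eps <- 1e-5
  for (nm in names(W)) {
    idx <- seq_len(min(4, length(W[[nm]])))
    for (i in idx) {
      Wp <- W; Wp[[nm]][i] <- Wp[[nm]][i] + eps
      Wm <- W; Wm[[nm]][i] <- Wm[[nm]][i] - eps
      num <- (loss_at(Wp) - loss_at(Wm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   info = sprintf("tensor %s[%d]", nm, i))
    }
  }
})

test_that("a perfect provisional signal is learned to high AUC", {
  lab <- replicate(6, blocky(), simplify = FALSE)
  prov <- lapply(lab, function(l) as.numeric(l))
  pairs <- make_sequences(series_of(prov[1:4]), states_of(lab[1:4]), 20L)
  m <- train_stage2(pairs, tiny_cnn(epochs = 15L, train_stride_min = 2L))
  held <- make_sequences(series_of(prov[5:6], pid = "T02"),
                         states_of(lab[5:6], pid = "T02"), 20L)
  p <- workmode:::cnn_predict_mat(m$weights, held$X, m$config)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(participant_auc(p, held$y), 0.99)
})

test_that("training refuses a one-class target", {
  lab <- list(rep(1L, 1095))
  pairs <- make_sequences(series_of(list(runif(1095))), states_of(lab), 20L)
  expect_error(train_stage2(pairs, tiny_cnn()), "both classes")
})

test_that("prediction keeps the grid, respects warm-up and is deterministic", {
  set.seed(21)
  lab <- replicate(4, blocky(), simplify = FALSE)
  prov <- lapply(lab, function(l) pmin(1, pmax(0, l + rnorm(1095, 0, 0.3))))
  cfg <- tiny_cnn(epochs = 10L)
  pairs <- make_sequences(series_of(prov), states_of(lab), cfg$lookback_min)
  m <- train_stage2(pairs, cfg)
  s <- series_of(prov[1:2])
  out <- predict_series(m, s)
  expect_equal(nrow(out), nrow(s))
  expect_true(all(out$final >= 0 & out$final <= 1))
  L <- cfg$lookback_min
  first_day <- out[out$date == min(out$date), ]
  expect_equal(first_day$final[1:L], first_day$provisional[1:L])  # warm-up
  expect_identical(out, predict_series(m, s))

  # smoothing: fewer threshold crossings than the noisy input
  crossings <- function(x) sum(diff(x > 0.5) != 0)
  expect_lt(crossings(first_day$final), crossings(first_day$provisional))
})

test_that("temporal smoothing lifts AUC on autocorrelated states but not on iid minutes", {
  set.seed(31)
  noisy <- function(l) pmin(1, pmax(0, l + rnorm(length(l), 0, 0.45)))
  # autocorrelated day structure
  lab_ac <- replicate(6, blocky(), simplify = FALSE)
  prov_ac <- lapply(lab_ac, noisy)
  cfg <- tiny_cnn(epochs = 15L)
  tr <- make_sequences(series_of(prov_ac[1:4]), states_of(lab_ac[1:4]),
                       cfg$lookback_min)
  m <- train_stage2(tr, cfg)
  te <- make_sequences(series_of(prov_ac[5:6], pid = "T02"),
                       states_of(lab_ac[5:6], pid = "T02"), cfg$lookback_min)
  gain_ac <- participant_auc(workmode:::cnn_predict_mat(m$weights, te$X, cfg),
                             te$y) - participant_auc(te$X[, cfg$lookback_min], te$y)

  # iid minutes: no temporal structure to exploit
  lab_iid <- replicate(6, rbinom(1095, 1, 0.5), simplify = FALSE)
  prov_iid <- lapply(lab_iid, noisy)
  tr2 <- make_sequences(series_of(prov_iid[1:4]), states_of(lab_iid[1:4]),
                        cfg$lookback_min)
  m2 <- train_stage2(tr2, cfg)
  te2 <- make_sequences(series_of(prov_iid[5:6], pid = "T02"),
                        states_of(lab_iid[5:6], pid = "T02"), cfg$lookback_min)
  gain_iid <- participant_auc(workmode:::cnn_predict_mat(m2$weights, te2$X, cfg),
                              te2$y) - participant_auc(te2$X[, cfg$lookback_min], te2$y)

  expect_gt(gain_ac, 0.03)       # clear gain under autocorrelation
  expect_lt(gain_iid, gain_ac)   # the gain mechanism is the autocorrelation
  expect_lt(abs(gain_iid), 0.05) # and shrinks toward zero without it
})

test_that("stage-2 accessors report the fit", {
  lab <- replicate(3, blocky(), simplify = FALSE)
  prov <- lapply(lab, function(l) pmin(1, pmax(0, l + rnorm(1095, 0, 0.2))))
  cfg <- tiny_cnn(epochs = 6L)
  m <- train_stage2(make_sequences(series_of(prov), states_of(lab),
                                   cfg$lookback_min), cfg)
  expect_equal(names(tidy(m)), c("epoch", "train_loss", "val_loss"))
  gl <- glance(m)
  expect_equal(gl$lookback_min, cfg$lookback_min)
  expect_gt(gl$n_params, 0)
})
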
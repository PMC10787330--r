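# Independent brute-force references the implementation is checked against.

# all-pairs AUC with half credit for ties, O(n^2)
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels != 1]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# direct interval arithmetic for the 5-feature scheme on one window [a, b)
# episodes: data.frame(app, s, e); notifs: data.frame(app, sec)
oracle_window_features <- function(episodes, notifs, a, b, vocab) {
  out <- numeric(0)
  for (app in vocab) {
    ep <- episodes[episodes$app == app, , drop = FALSE]
    ep <- ep[order(ep$s), , drop = FALSE]
    nt <- sort(notifs$sec[notifs$app == app])
    f1 <- 0
    for (i in seq_len(nrow(ep))) f1 <- f1 + max(0, min(ep$e[i], b) - max(ep$s[i], a))
    f2 <- 0; f3 <- 0
    for (t in nt[nt >= a & nt < b]) {
      inside <- any(t >= ep$s & t < ep$e)
      if (inside) f2 <- f2 + 1 else f3 <- f3 + 1
    }
    rts <- c(); its <- c()
    for (i in seq_len(nrow(ep))) {
      if (ep$s[i] < a || ep$s[i] >= b) next
      prev_end <- if (i > 1) ep$e[i - 1] else 0
      cand <- nt[nt < ep$s[i] & nt >= prev_end]
      if (length(cand)) {
        rts <- c(rts, ep$s[i] - max(cand))
        its <- c(its, ep$e[i] - ep$s[i])
      }
    }
    out <- c(out, f1, f2, f3,
             if (length(rts)) mean(rts) else NA_real_,
             if (length(its)) mean(its) else NA_real_)
  }
  names(out) <- as.vector(t(outer(vocab, paste0("_f", 1:5), paste0)))
  out
}

# exhaustive run-scan for the geofence state machine, written against the
# rules directly: begin at the first fix of a continuously-in-range stretch
# spanning >= confirm seconds; end at the last in-range fix before a
# continuously-out stretch (or fix gap) spanning >= confirm seconds
oracle_intervals <- function(tt, inr, confirm) {
  n <- length(tt)
  res <- list()
  gap_after <- c(diff(tt) > confirm, FALSE)
  i <- 1
  while (i <= n) {
    if (!inr[i]) { i <- i + 1; next }
    # maximal continuously-in-range stretch from i (no out fix, no big gap)
    j <- i
    while (j < n && inr[j + 1] && !gap_after[j]) j <- j + 1
    if (tt[j] - tt[i] < confirm) { i <- j + 1; next }
    start <- tt[i]; last_in <- tt[j]
    k <- j + 1
    while (k <= n) {
      if (gap_after[k - 1]) break           # silent gap acts as a stop
      if (inr[k]) {
        last_in <- tt[k]; k <- k + 1
      } else {
        m <- k
        while (m < n && !inr[m + 1] && !gap_after[m]) m <- m + 1
        qualified <- (tt[m] - tt[k] >= confirm) || m == n ||
          (m < n && gap_after[m])
        k <- m + 1
        if (qualified) break
      }
    }
    res[[length(res) + 1]] <- c(start, last_in)
    i <- max(k, j + 1)
  }
  res
}

# stack matcher for episode extraction (single participant-day, sorted)
oracle_episodes <- function(kinds, times, apps) {
  open <- NULL
  out <- list()
  for (i in seq_along(kinds)) {
    if (kinds[i] == "screen_on") {
      if (!is.null(open)) {
        out[[length(out) + 1]] <- c(open$t, times[i])
      }
      open <- list(t = times[i], app = apps[i])
    } else if (kinds[i] == "screen_off" && !is.null(open)) {
      out[[length(out) + 1]] <- c(open$t, times[i])
      open <- NULL
    }
  }
  out
}
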
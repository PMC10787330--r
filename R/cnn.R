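# A compact 1-D convolutional network, written directly in vectorised R
# (im2col + BLAS matrix products). Structure is fixed: 3 convolution layers
# (ReLU; max pooling after the first two, global average pooling after the
# third) and 2 fully connected layers (ReLU, then a single sigmoid unit).
# Trained with Adam on binary cross-entropy.
#
# Activation matrices are laid out (B*P) x C with row index b + (p-1)*B:
# all batch rows of one sequence position are contiguous, so im2col and
# pooling are pure row-index gathers.

cnn_dims <- function(cfg) {
  K <- cfg$kernels
  P1 <- cfg$lookback_min - K[1] + 1L
  Q1 <- P1 %/% 2L
  P2 <- Q1 - K[2] + 1L
  Q2 <- P2 %/% 2L
  P3 <- Q2 - K[3] + 1L
  list(P1 = P1, Q1 = Q1, P2 = P2, Q2 = Q2, P3 = P3)
}

cnn_init <- function(cfg) {
  K <- cfg$kernels; Fl <- cfg$filters; H <- cfg$fc_width
  he <- function(nr, nc, fan) matrix(rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  local_rng(cfg$seed, list(
    W1 = he(K[1], Fl[1], K[1]), b1 = numeric(Fl[1]),
    W2 = he(K[2] * Fl[1], Fl[2], K[2] * Fl[1]), b2 = numeric(Fl[2]),
    W3 = he(K[3] * Fl[2], Fl[3], K[3] * Fl[2]), b3 = numeric(Fl[3]),
    W4 = he(Fl[3], H, Fl[3]), b4 = numeric(H),
    W5 = he(H, 1L, H), b5 = numeric(1L)
  ))
}

# row-index helpers for batch size B
cnn_idx <- function(B, cfg) {
  dm <- cnn_dims(cfg)
  pos_rows <- function(P) lapply(seq_len(P), function(p) (p - 1L) * B + seq_len(B))
  # im2col gather rows: for tap k, rows of positions (1:P_out) + k - 1
  gather <- function(P_out) lapply(seq_len(max(cfg$kernels)), function(k) {
    as.vector(outer(seq_len(B), (seq_len(P_out) + k - 2L) * B, "+"))
  })
  pool_idx <- function(P) list(
    odd = as.vector(outer(seq_len(B), (seq(1L, P, 2L) - 1L) * B, "+")),
    even = as.vector(outer(seq_len(B), (seq(2L, P, 2L) - 1L) * B, "+"))
  )
  list(
    dm = dm, B = B,
    ci1 = as.vector(outer(seq_len(dm$P1), 0:(cfg$kernels[1] - 1L), "+")),
    g2 = gather(dm$P2)[seq_len(cfg$kernels[2])],
    g3 = gather(dm$P3)[seq_len(cfg$kernels[3])],
    pool1 = pool_idx(dm$P1), pool2 = pool_idx(dm$P2),
    rows3 = pos_rows(dm$P3)
  )
}

addb <- function(Z, b) Z + rep(b, each = nrow(Z))
relu <- function(x) {
  x[x < 0] <- 0
  x
}
sigmoid <- function(x) 1 / (1 + exp(-x))

im2col_mc <- function(U, gathers, K, C) {
  # U: (B*P_in) x C -> (B*P_out) x (K*C), tap-major column blocks
  out <- matrix(0, length(gathers[[1]]) %/% 1L, K * C)
  for (k in seq_len(K)) {
    out[, (k - 1L) * C + seq_len(C)] <- U[gathers[[k]], , drop = FALSE]
  }
  out
}

col2im_mc <- function(dM, gathers, K, C, n_in) {
  dU <- matrix(0, n_in, C)
  for (k in seq_len(K)) {
    idx <- gathers[[k]]
    dU[idx, ] <- dU[idx, , drop = FALSE] + dM[, (k - 1L) * C + seq_len(C), drop = FALSE]
  }
  dU
}

cnn_forward <- function(W, X, cfg, ix, keep = FALSE) {
  K <- cfg$kernels; Fl <- cfg$filters
  B <- nrow(X); dm <- ix$dm

  M1 <- X[, ix$ci1, drop = FALSE]
  dim(M1) <- c(B * dm$P1, K[1])
  A1 <- relu(addb(M1 %*% W$W1, W$b1))                    # (B*P1) x F1
  o1 <- A1[ix$pool1$odd, , drop = FALSE]
  e1 <- A1[ix$pool1$even, , drop = FALSE]
  m1 <- o1 >= e1
  U1 <- pmax(o1, e1)                                     # (B*Q1) x F1

  M2 <- im2col_mc(U1, ix$g2, K[2], Fl[1])
  A2 <- relu(addb(M2 %*% W$W2, W$b2))                    # (B*P2) x F2
  o2 <- A2[ix$pool2$odd, , drop = FALSE]
  e2 <- A2[ix$pool2$even, , drop = FALSE]
  m2 <- o2 >= e2
  U2 <- pmax(o2, e2)                                     # (B*Q2) x F2

  M3 <- im2col_mc(U2, ix$g3, K[3], Fl[2])
  A3 <- relu(addb(M3 %*% W$W3, W$b3))                    # (B*P3) x F3
  G <- Reduce(`+`, lapply(ix$rows3, function(r) A3[r, , drop = FALSE])) / dm$P3

  H1 <- relu(addb(G %*% W$W4, W$b4))                     # B x H
  p <- sigmoid(addb(H1 %*% W$W5, W$b5))[, 1]             # B
  if (!keep) return(p)
  list(p = p, M1 = M1, A1 = A1, m1 = m1, U1 = U1, M2 = M2, A2 = A2,
       m2 = m2, U2 = U2, M3 = M3, A3 = A3, G = G, H1 = H1)
}

cnn_backward <- function(W, cache, y, cfg, ix) {
  K <- cfg$kernels; Fl <- cfg$filters
  dm <- ix$dm; B <- ix$B

  dZ5 <- matrix((cache$p - y) / B, ncol = 1)             # BCE + sigmoid
  gW5 <- crossprod(cache$H1, dZ5); gb5 <- colSums(dZ5)
  dH1 <- dZ5 %*% t(W$W5)
  dZ4 <- dH1 * (cache$H1 > 0)
  gW4 <- crossprod(cache$G, dZ4); gb4 <- colSums(dZ4)
  dG <- dZ4 %*% t(W$W4)

  dA3 <- matrix(0, B * dm$P3, Fl[3])
  share <- dG / dm$P3
  for (r in ix$rows3) dA3[r, ] <- share
  dZ3 <- dA3 * (cache$A3 > 0)
  gW3 <- crossprod(cache$M3, dZ3); gb3 <- colSums(dZ3)
  dM3 <- dZ3 %*% t(W$W3)
  dU2 <- col2im_mc(dM3, ix$g3, K[3], Fl[2], B * dm$Q2)

  dA2 <- matrix(0, B * dm$P2, Fl[2])
  dA2[ix$pool2$odd, ] <- dU2 * cache$m2
  dA2[ix$pool2$even, ] <- dU2 * !cache$m2
  dZ2 <- dA2 * (cache$A2 > 0)
  gW2 <- crossprod(cache$M2, dZ2); gb2 <- colSums(dZ2)
  dM2 <- dZ2 %*% t(W$W2)
  dU1 <- col2im_mc(dM2, ix$g2, K[2], Fl[1], B * dm$Q1)

  dA1 <- matrix(0, B * dm$P1, Fl[1])
  dA1[ix$pool1$odd, ] <- dU1 * cache$m1
  dA1[ix$pool1$even, ] <- dU1 * !cache$m1
  dZ1 <- dA1 * (cache$A1 > 0)
  gW1 <- crossprod(cache$M1, dZ1); gb1 <- colSums(dZ1)

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4, W5 = gW5, b5 = gb5)
}

adam_init <- function(W) list(m = lapply(W, function(w) w * 0),
                              v = lapply(W, function(w) w * 0), t = 0)

adam_step <- function(W, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (nm in names(W)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    W[[nm]] <- W[[nm]] - lr * (st$m[[nm]] / c1) / (sqrt(st$v[[nm]] / c2) + eps)
  }
  list(W = W, st = st)
}

bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

cnn_predict_mat <- function(W, X, cfg, chunk = 4096L) {
  n <- nrow(X)
  if (n == 0) return(numeric())
  out <- numeric(n)
  at <- 1L
  while (at <= n) {
    idx <- at:min(n, at + chunk - 1L)
    ix <- cnn_idx(length(idx), cfg)
    out[idx] <- cnn_forward(W, X[idx, , drop = FALSE], cfg, ix)
    at <- at + chunk
  }
  out
}

# minibatch Adam with early stopping on a held-out validation split;
# restores the best weights seen
cnn_train <- function(X, y, cfg) {
  n <- nrow(X)
  local_rng(cfg$seed + 1L, {
    W <- cnn_init(cfg)
    st <- adam_init(W)
    n_val <- max(1L, round(cfg$val_frac * n))
    vi <- sample.int(n, n_val)
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    Xt <- X[-vi, , drop = FALSE]; yt <- y[-vi]
    nt <- nrow(Xt)
    bs <- min(cfg$batch_size, nt)
    ix_full <- cnn_idx(bs, cfg)
    history <- list()
    best <- list(loss = Inf, W = W, epoch = 0L)
    stale <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(nt)
      tl <- 0; nb <- 0L
      at <- 1L
      while (at <= nt) {
        idx <- ord[at:min(nt, at + bs - 1L)]
        ix <- if (length(idx) == bs) ix_full else cnn_idx(length(idx), cfg)
        cache <- cnn_forward(W, Xt[idx, , drop = FALSE], cfg, ix, keep = TRUE)
        g <- cnn_backward(W, cache, yt[idx], cfg, ix)
        up <- adam_step(W, g, st, cfg$lr)
        W <- up$W; st <- up$st
        tl <- tl + bce(cache$p, yt[idx]); nb <- nb + 1L
        at <- at + bs
      }
      vl <- bce(cnn_predict_mat(W, Xv, cfg), yv)
      history[[epoch]] <- tibble(epoch = epoch, train_loss = tl / nb,
                                 val_loss = vl)
      if (vl < best$loss - 1e-5) {
        best <- list(loss = vl, W = W, epoch = epoch)
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= cfg$patience) break
      }
    }
    list(weights = best$W, best_epoch = best$epoch,
         val_loss = best$loss, history = list_rbind(history))
  })
}
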
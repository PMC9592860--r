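# Batched forward/backward passes used by the training loop. Cells of a
# mini-batch are stacked cell-major into a (B*L) x d_model token matrix;
# everything position-wise (embedding, layer norm, FFN, convolution,
# classifier) is a single matrix operation, and only the L x L attention
# softmax loops over cells. Gradients are exact analytic backprop; a
# finite-difference test pins them down, and a separate test checks that
# this path reproduces the single-sequence primitives in nn_ops.R.

rows_of <- function(b, L) ((b - 1L) * L + 1L):(b * L)

relu <- function(x) { x[x < 0] <- 0; x }

dropout_mask <- function(nr, nc, p) {
  if (p <= 0) return(NULL)
  matrix((stats::runif(nr * nc) >= p) / (1 - p), nr, nc)
}

ln_fwd <- function(X, g, b, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sd_ <- sqrt(rowMeans(Xc^2) + eps)
  xhat <- Xc / sd_
  list(Y = sweep(sweep(xhat, 2, g, "*"), 2, b, "+"), xhat = xhat, sd = sd_)
}

ln_bwd <- function(dY, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dY * xhat)
  db <- colSums(dY)
  dxhat <- sweep(dY, 2, g, "*")
  dX <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) / cache$sd
  list(dX = dX, dg = dg, db = db)
}

ffn_fwd <- function(X, p) {
  H <- relu(sweep(X %*% p$W1, 2, p$b1, "+"))
  list(Y = sweep(H %*% p$W2, 2, p$b2, "+"), X = X, H = H)
}

ffn_bwd <- function(dY, cache, p) {
  dW2 <- crossprod(cache$H, dY)
  db2 <- colSums(dY)
  dH <- dY %*% t(p$W2)
  dZ1 <- dH * (cache$H > 0)
  list(dX = dZ1 %*% t(p$W1),
       g = list(W1 = crossprod(cache$X, dZ1), b1 = colSums(dZ1),
                W2 = dW2, b2 = db2))
}

# self-attention over B stacked sequences of length L
mha_fwd <- function(X, p, n_heads, B, L) {
  dm <- ncol(X); dk <- dm %/% n_heads
  Q <- X %*% p$Wq; K <- X %*% p$Wk; V <- X %*% p$Wv
  O <- matrix(0, nrow(X), dm)
  A <- lapply(seq_len(n_heads), function(h) matrix(0, nrow(X), L))
  scal <- 1 / sqrt(dk)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- Q[, cols, drop = FALSE]; Kh <- K[, cols, drop = FALSE]
    Vh <- V[, cols, drop = FALSE]
    for (b in seq_len(B)) {
      rb <- rows_of(b, L)
      Ab <- softmax_rows(Qh[rb, , drop = FALSE] %*%
                           t(Kh[rb, , drop = FALSE]) * scal)
      A[[h]][rb, ] <- Ab
      O[rb, cols] <- Ab %*% Vh[rb, , drop = FALSE]
    }
  }
  list(Y = O %*% p$Wo, X = X, Q = Q, K = K, V = V, O = O, A = A)
}

mha_bwd <- function(dY, cache, p, n_heads, B, L) {
  dm <- ncol(dY); dk <- dm %/% n_heads
  scal <- 1 / sqrt(dk)
  dWo <- crossprod(cache$O, dY)
  dO <- dY %*% t(p$Wo)
  dQ <- matrix(0, nrow(dY), dm); dK <- dQ; dV <- dQ
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    Qh <- cache$Q[, cols, drop = FALSE]; Kh <- cache$K[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    for (b in seq_len(B)) {
      rb <- rows_of(b, L)
      Ab <- cache$A[[h]][rb, , drop = FALSE]
      dOh <- dO[rb, cols, drop = FALSE]
      dV[rb, cols] <- dV[rb, cols, drop = FALSE] + t(Ab) %*% dOh
      dA <- dOh %*% t(Vh[rb, , drop = FALSE])
      dS <- Ab * (dA - rowSums(Ab * dA))
      dQ[rb, cols] <- dS %*% Kh[rb, , drop = FALSE] * scal
      dK[rb, cols] <- t(dS) %*% Qh[rb, , drop = FALSE] * scal
    }
  }
  list(dX = dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv),
       g = list(Wq = crossprod(cache$X, dQ), Wk = crossprod(cache$X, dK),
                Wv = crossprod(cache$X, dV), Wo = dWo))
}

# cross-attention of one query token per cell over its encoder output
cross_fwd <- function(Q0, E, p, n_heads, B, L) {
  dm <- ncol(Q0); dk <- dm %/% n_heads
  Qp <- Q0 %*% p$Wq; Kp <- E %*% p$Wk; Vp <- E %*% p$Wv
  O <- matrix(0, B, dm)
  A <- lapply(seq_len(n_heads), function(h) matrix(0, B, L))
  scal <- 1 / sqrt(dk)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    for (b in seq_len(B)) {
      rb <- rows_of(b, L)
      a <- softmax_rows(Qp[b, cols, drop = FALSE] %*%
                          t(Kp[rb, cols, drop = FALSE]) * scal)
      A[[h]][b, ] <- a
      O[b, cols] <- a %*% Vp[rb, cols, drop = FALSE]
    }
  }
  list(Y = O %*% p$Wo, Q0 = Q0, E = E, Qp = Qp, Kp = Kp, Vp = Vp, O = O,
       A = A)
}

cross_bwd <- function(dY, cache, p, n_heads, B, L) {
  dm <- ncol(dY); dk <- dm %/% n_heads
  scal <- 1 / sqrt(dk)
  dWo <- crossprod(cache$O, dY)
  dO <- dY %*% t(p$Wo)
  dQp <- matrix(0, B, dm)
  dKp <- matrix(0, nrow(cache$E), dm); dVp <- dKp
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dk + 1L):(h * dk)
    for (b in seq_len(B)) {
      rb <- rows_of(b, L)
      a <- cache$A[[h]][b, , drop = FALSE]
      dOh <- dO[b, cols, drop = FALSE]
      dVp[rb, cols] <- dVp[rb, cols, drop = FALSE] + t(a) %*% dOh
      da <- dOh %*% t(cache$Vp[rb, cols, drop = FALSE])
      dS <- a * (da - sum(a * da))
      dQp[b, cols] <- dS %*% cache$Kp[rb, cols, drop = FALSE] * scal
      dKp[rb, cols] <- dKp[rb, cols, drop = FALSE] +
        t(dS) %*% cache$Qp[b, cols, drop = FALSE] * scal
    }
  }
  list(dQ0 = dQp %*% t(p$Wq),
       dE = dKp %*% t(p$Wk) + dVp %*% t(p$Wv),
       g = list(Wq = crossprod(cache$Q0, dQp), Wk = crossprod(cache$E, dKp),
                Wv = crossprod(cache$E, dVp), Wo = dWo))
}

# zero-padded same-length im2col indices for B stacked sequences
conv_indices <- function(B, L, kernel) {
  half <- (kernel - 1L) %/% 2L
  tok <- rep(seq_len(L), B)
  base <- rep(seq(0L, by = L, length.out = B), each = L)
  pad <- B * L + 1L
  lapply(seq_len(kernel), function(j) {
    st <- tok + (j - 1L - half)
    ifelse(st >= 1L & st <= L, base + st, pad)
  })
}

# full batched forward pass; returns caches needed for backprop
nn_forward_batch <- function(params, F_, cfg, train = FALSE) {
  B <- nrow(F_); L <- cfg$n_features; dm <- cfg$d_model
  drop_p <- if (train) cfg$dropout else 0
  it <- rep(seq_len(L), B)
  Fvec <- as.vector(t(F_))
  PE <- pe_matrix(L, dm)
  X <- Fvec * params$emb$dir[it, , drop = FALSE] +
    params$emb$bias[it, , drop = FALSE] + PE[it, , drop = FALSE]
  cache <- list(B = B, it = it, Fvec = Fvec, enc = list())
  for (li in seq_along(params$enc)) {
    lp <- params$enc[[li]]
    lc <- list()
    lc$attn <- mha_fwd(X, lp$attn, cfg$n_heads, B, L)
    A <- lc$attn$Y
    lc$mask1 <- dropout_mask(nrow(A), dm, drop_p)
    if (!is.null(lc$mask1)) A <- A * lc$mask1
    if (cfg$residual_norm) {
      lc$Xin <- X
      lc$ln1 <- ln_fwd(X + A, lp$ln1$g, lp$ln1$b)
      X1 <- lc$ln1$Y
    } else X1 <- A
    lc$ffn <- ffn_fwd(X1, lp$ffn)
    Fo <- lc$ffn$Y
    lc$mask2 <- dropout_mask(nrow(Fo), dm, drop_p)
    if (!is.null(lc$mask2)) Fo <- Fo * lc$mask2
    if (cfg$residual_norm) {
      lc$X1 <- X1
      lc$ln2 <- ln_fwd(X1 + Fo, lp$ln2$g, lp$ln2$b)
      X <- lc$ln2$Y
    } else X <- Fo
    cache$enc[[li]] <- lc
  }
  E <- X
  Lc <- seq_length(cfg)
  if (cfg$use_decoder) {
    dp <- params$dec
    dc <- list()
    Q0 <- matrix(dp$query, B, dm, byrow = TRUE)
    dc$cross <- cross_fwd(Q0, E, dp$attn, cfg$n_heads, B, L)
    A <- dc$cross$Y
    dc$mask1 <- dropout_mask(B, dm, drop_p)
    if (!is.null(dc$mask1)) A <- A * dc$mask1
    if (cfg$residual_norm) {
      dc$ln1 <- ln_fwd(Q0 + A, dp$ln1$g, dp$ln1$b)
      S <- dc$ln1$Y
    } else S <- A
    dc$ffn <- ffn_fwd(S, dp$ffn)
    Fo <- dc$ffn$Y
    dc$mask2 <- dropout_mask(B, dm, drop_p)
    if (!is.null(dc$mask2)) Fo <- Fo * dc$mask2
    if (cfg$residual_norm) {
      dc$S1 <- S
      dc$ln2 <- ln_fwd(S + Fo, dp$ln2$g, dp$ln2$b)
      S <- dc$ln2$Y
    } else S <- Fo
    cache$dec <- dc
    # prepend the summary token to every cell's sequence
    Xf <- matrix(0, B * Lc, dm)
    sum_rows <- seq(1L, by = Lc, length.out = B)
    Xf[sum_rows, ] <- S
    Xf[-sum_rows, ] <- E
    cache$sum_rows <- sum_rows
  } else Xf <- E
  idx <- conv_indices(B, Lc, cfg$conv_kernel)
  Xp <- rbind(Xf, 0)
  im2col <- do.call(cbind, lapply(idx, function(i) Xp[i, , drop = FALSE]))
  Co <- relu(sweep(im2col %*% params$conv$W, 2, params$conv$b, "+"))
  Flat <- matrix(as.vector(t(Co)), B, Lc * cfg$conv_channels, byrow = TRUE)
  logits <- sweep(Flat %*% params$cls$W, 2, params$cls$b, "+")
  cache$conv <- list(idx = idx, im2col = im2col, Co = Co, Flat = Flat,
                     Lc = Lc, n_rows = B * Lc)
  # stable softmax
  probs <- softmax_rows(logits)
  list(probs = probs, logits = logits, cache = cache)
}

nn_backward_batch <- function(params, fwd, labels, cfg) {
  cache <- fwd$cache
  B <- cache$B; L <- cfg$n_features; dm <- cfg$d_model
  k <- cfg$n_classes
  Lc <- cache$conv$Lc
  g <- list()
  # loss gradient w.r.t. logits (mean cross-entropy)
  dlogits <- fwd$probs
  dlogits[cbind(seq_len(B), labels)] <-
    dlogits[cbind(seq_len(B), labels)] - 1
  dlogits <- dlogits / B
  g$cls <- list(W = crossprod(cache$conv$Flat, dlogits),
                b = colSums(dlogits))
  dFlat <- dlogits %*% t(params$cls$W)
  C <- cfg$conv_channels
  dCo <- matrix(as.vector(t(dFlat)), ncol = C, byrow = TRUE)
  dZ <- dCo * (cache$conv$Co > 0)
  g$conv <- list(W = crossprod(cache$conv$im2col, dZ), b = colSums(dZ))
  dim2col <- dZ %*% t(params$conv$W)
  dXf <- matrix(0, cache$conv$n_rows, dm)
  for (j in seq_along(cache$conv$idx)) {
    i <- cache$conv$idx[[j]]
    keep <- i <= cache$conv$n_rows
    block <- dim2col[, ((j - 1L) * dm + 1L):(j * dm), drop = FALSE]
    dXf[i[keep], ] <- dXf[i[keep], , drop = FALSE] +
      block[keep, , drop = FALSE]
  }
  if (cfg$use_decoder) {
    dp <- params$dec
    dc <- cache$dec
    dS <- dXf[cache$sum_rows, , drop = FALSE]
    dE <- dXf[-cache$sum_rows, , drop = FALSE]
    g$dec <- list()
    if (cfg$residual_norm) {
      l2 <- ln_bwd(dS, dc$ln2, dp$ln2$g)
      g$dec$ln2 <- list(g = l2$dg, b = l2$db)
      dFo <- l2$dX; dS1 <- l2$dX
    } else { dFo <- dS; dS1 <- matrix(0, B, dm) }
    if (!is.null(dc$mask2)) dFo <- dFo * dc$mask2
    fb <- ffn_bwd(dFo, dc$ffn, dp$ffn)
    g$dec$ffn <- fb$g
    dS1 <- dS1 + fb$dX
    if (cfg$residual_norm) {
      l1 <- ln_bwd(dS1, dc$ln1, dp$ln1$g)
      g$dec$ln1 <- list(g = l1$dg, b = l1$db)
      dA <- l1$dX; dQ0 <- l1$dX
    } else { dA <- dS1; dQ0 <- matrix(0, B, dm) }
    if (!is.null(dc$mask1)) dA <- dA * dc$mask1
    cb <- cross_bwd(dA, dc$cross, dp$attn, cfg$n_heads, B, L)
    g$dec$attn <- cb$g
    dQ0 <- dQ0 + cb$dQ0
    g$dec$query <- matrix(colSums(dQ0), 1L, dm)
    dE <- dE + cb$dE
    dX <- dE
  } else dX <- dXf
  g$enc <- vector("list", length(params$enc))
  for (li in rev(seq_along(params$enc))) {
    lp <- params$enc[[li]]
    lc <- cache$enc[[li]]
    gl <- list()
    if (cfg$residual_norm) {
      l2 <- ln_bwd(dX, lc$ln2, lp$ln2$g)
      gl$ln2 <- list(g = l2$dg, b = l2$db)
      dFo <- l2$dX; dX1 <- l2$dX
    } else { dFo <- dX; dX1 <- matrix(0, nrow(dX), dm) }
    if (!is.null(lc$mask2)) dFo <- dFo * lc$mask2
    fb <- ffn_bwd(dFo, lc$ffn, lp$ffn)
    gl$ffn <- fb$g
    dX1 <- dX1 + fb$dX
    if (cfg$residual_norm) {
      l1 <- ln_bwd(dX1, lc$ln1, lp$ln1$g)
      gl$ln1 <- list(g = l1$dg, b = l1$db)
      dA <- l1$dX; dXin <- l1$dX
    } else { dA <- dX1; dXin <- matrix(0, nrow(dX1), dm) }
    if (!is.null(lc$mask1)) dA <- dA * lc$mask1
    ab <- mha_bwd(dA, lc$attn, lp$attn, cfg$n_heads, B, L)
    gl$attn <- ab$g
    dX <- dXin + ab$dX
    g$enc[[li]] <- gl
  }
  it <- cache$it
  g$emb <- list(dir = unname(rowsum(dX * cache$Fvec, it)),
                bias = unname(rowsum(dX, it)))
  # gradient w.r.t. the input features is not needed for training
  g
}

# mean cross-entropy from logits via log-sum-exp (exact, no clamping)
logit_loss <- function(logits, labels) {
  m <- apply(logits, 1, max)
  lse <- m + log(rowSums(exp(logits - m)))
  mean(lse - logits[cbind(seq_along(labels), labels)])
}

# ---- Adam ------------------------------------------------------------

zero_like <- function(p)
  if (is.list(p)) lapply(p, zero_like) else p * 0

adam_update <- function(p, g, m, v, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  if (is.list(p)) {
    out_p <- p; out_m <- m; out_v <- v
    for (nm in names(p)) {
      if (is.null(g[[nm]])) next
      r <- adam_update(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t,
                       beta1, beta2, eps)
      out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
    }
    list(p = out_p, m = out_m, v = out_v)
  } else {
    m2 <- beta1 * m + (1 - beta1) * g
    v2 <- beta2 * v + (1 - beta2) * g^2
    mh <- m2 / (1 - beta1^t)
    vh <- v2 / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}

sgd_update <- function(p, g, lr) {
  if (is.list(p)) {
    for (nm in names(p))
      if (!is.null(g[[nm]])) p[[nm]] <- sgd_update(p[[nm]], g[[nm]], lr)
    p
  } else p - lr * g
}

# ---- training loop ---------------------------------------------------

# features: n x d matrix of (positively shifted) discriminant coordinates
# labels: integer classes 1..k
train_network <- function(features, labels, cfg, tcfg, seed = cfg$seed,
                          verbose = FALSE) {
  n <- nrow(features)
  stopifnot(length(labels) == n, n >= 1)
  cfg$seed <- as.integer(seed)
  params <- init_model_params(cfg)
  set.seed(as.integer(seed) + 1L)
  m <- zero_like(params); v <- zero_like(params)
  t_step <- 0L
  history <- numeric(0)
  best <- Inf; stall <- 0L
  for (epoch in seq_len(tcfg$epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = tcfg$batch_size)
    ep_loss <- 0
    for (s in starts) {
      idx <- perm[s:min(s + tcfg$batch_size - 1L, n)]
      fwd <- nn_forward_batch(params, features[idx, , drop = FALSE], cfg,
                              train = TRUE)
      loss <- logit_loss(fwd$logits, labels[idx])
      if (!is.finite(loss))
        stop("non-finite training loss at epoch ", epoch,
             "; try a lower learning rate")
      grads <- nn_backward_batch(params, fwd, labels[idx], cfg)
      if (identical(tcfg$optimizer, "sgd")) {
        params <- sgd_update(params, grads, tcfg$learning_rate)
      } else {
        t_step <- t_step + 1L
        st <- adam_update(params, grads, m, v, tcfg$learning_rate, t_step)
        params <- st$p; m <- st$m; v <- st$v
      }
      ep_loss <- ep_loss + loss * length(idx)
    }
    ep_loss <- ep_loss / n
    history <- c(history, ep_loss)
    if (verbose) message(sprintf("epoch %3d  loss %.5f", epoch, ep_loss))
    if (ep_loss < best - tcfg$min_delta) {
      best <- ep_loss; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= tcfg$patience) break
    }
  }
  class(params) <- "model_parameters"
  list(params = params,
       history = data.frame(epoch = seq_along(history), loss = history))
}

# batched prediction on a feature matrix; dropout disabled
predict_network <- function(params, features, cfg, chunk = 1024L) {
  n <- nrow(features)
  probs <- matrix(0, n, cfg$n_classes)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    probs[idx, ] <- nn_forward_batch(params,
                                     features[idx, , drop = FALSE],
                                     cfg, train = FALSE)$probs
  }
  probs
}
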
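# Internal neural-network engine: 1-D convolution (same padding) + ReLU,
# non-overlapping max-pooling, a single LSTM layer (sequence output),
# single-head scaled dot-product self-attention over the LSTM states,
# global average pooling over time, a ReLU dense layer and a 2-unit softmax
# head. Forward, full backward (including BPTT and attention), and Adam.
#
# Shapes: a batch is an array B x T x C (segments x frames x channels).
# Convolutions use im2col; pooling records argmax positions for the backward
# routing. All gradients are validated against finite differences in the
# test suite.

.sigmoid <- function(x) 1 / (1 + exp(-x))

.softmax <- function(logits) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

.addRowVec <- function(M, v) M + rep(v, each = nrow(M))

.glorot <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

.nnTimeSteps <- function(frames, cfg) {
  t1 <- frames %/% cfg$poolSizes[1L]
  t2 <- t1 %/% cfg$poolSizes[2L]
  c(t1 = t1, t2 = t2)
}

.nnInitParams <- function(cfg, nChannels) {
  k <- cfg$convKernels; f <- cfg$convFilters
  H <- cfg$lstmUnits; D <- cfg$denseUnits
  bl <- numeric(4L * H)
  bl[H + seq_len(H)] <- 1  # forget-gate bias: remember by default
  list(
    Wc1 = .glorot(k[1L] * nChannels, f[1L]), bc1 = numeric(f[1L]),
    Wc2 = .glorot(k[2L] * f[1L], f[2L]), bc2 = numeric(f[2L]),
    Wl = .glorot(f[2L] + H, 4L * H), bl = bl,
    Wd1 = .glorot(H, D), bd1 = numeric(D),
    Wd2 = .glorot(D, 2L), bd2 = numeric(2L)
  )
}

# ---- convolution ------------------------------------------------------------

.convForward <- function(X, W, b, k) {
  d <- dim(X); B <- d[1L]; T <- d[2L]; C <- d[3L]
  padL <- (k - 1L) %/% 2L
  Tp <- T + k - 1L
  Xp <- array(0, c(B, Tp, C))
  Xp[, padL + seq_len(T), ] <- X
  Xcol <- matrix(0, B * T, k * C)
  for (o in seq_len(k)) {
    S <- Xp[, o:(o + T - 1L), , drop = FALSE]
    dim(S) <- c(B * T, C)
    Xcol[, ((o - 1L) * C + 1L):(o * C)] <- S
  }
  Z <- .addRowVec(Xcol %*% W, b)
  act <- Z > 0
  A <- Z * act
  dim(A) <- c(B, T, length(b))
  list(A = A, act = act, Xcol = Xcol, k = k, C = C, padL = padL,
       T = T, B = B)
}

.convBackward <- function(dA, cache, W) {
  B <- cache$B; T <- cache$T; C <- cache$C; k <- cache$k
  dZ <- dA
  dim(dZ) <- c(B * T, ncol(W))
  dZ <- dZ * cache$act
  dW <- crossprod(cache$Xcol, dZ)
  db <- colSums(dZ)
  dXcol <- tcrossprod(dZ, W)
  Tp <- T + k - 1L
  dXp <- array(0, c(B, Tp, C))
  for (o in seq_len(k)) {
    S <- dXcol[, ((o - 1L) * C + 1L):(o * C), drop = FALSE]
    dim(S) <- c(B, T, C)
    dXp[, o:(o + T - 1L), ] <- dXp[, o:(o + T - 1L), , drop = FALSE] + S
  }
  list(dX = dXp[, cache$padL + seq_len(T), , drop = FALSE], dW = dW, db = db)
}

# ---- max pooling -------------------------------------------------------------

.poolForward <- function(A, p) {
  d <- dim(A); B <- d[1L]; T <- d[2L]; F <- d[3L]
  T2 <- T %/% p
  if (T2 < 1L)
    stop("model: sequence shorter than the pooling receptive field")
  At <- A[, seq_len(T2 * p), , drop = FALSE]
  dim(At) <- c(B, p, T2, F)
  cur <- array(At[, 1L, , ], c(B, T2, F))
  arg <- array(1L, c(B, T2, F))
  if (p > 1L) for (i in 2:p) {
    cand <- array(At[, i, , ], c(B, T2, F))
    upd <- cand > cur
    cur[upd] <- cand[upd]
    arg[upd] <- i
  }
  list(P = cur, arg = arg, p = p, T = T, T2 = T2, B = B, F = F)
}

.poolBackward <- function(dP, cache) {
  B <- cache$B; F <- cache$F; p <- cache$p; T2 <- cache$T2
  dA <- array(0, c(B, p, T2, F))
  for (i in seq_len(p)) {
    sel <- cache$arg == i
    tmp <- array(0, c(B, T2, F))
    tmp[sel] <- dP[sel]
    dA[, i, , ] <- tmp
  }
  dim(dA) <- c(B, p * T2, F)
  if (cache$T > p * T2) {
    full <- array(0, c(B, cache$T, F))
    full[, seq_len(p * T2), ] <- dA
    dA <- full
  }
  dA
}

# ---- LSTM -------------------------------------------------------------------

.lstmForward <- function(Xs, W, b, H) {
  d <- dim(Xs); B <- d[1L]; T <- d[2L]; Fin <- d[3L]
  Hs <- array(0, c(B, T, H)); Cs <- array(0, c(B, T, H))
  Is <- array(0, c(B, T, H)); Fs <- array(0, c(B, T, H))
  Gs <- array(0, c(B, T, H)); Os <- array(0, c(B, T, H))
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  idxI <- seq_len(H); idxF <- H + idxI; idxG <- 2L * H + idxI
  idxO <- 3L * H + idxI
  for (t in seq_len(T)) {
    x <- array(Xs[, t, ], c(B, Fin))
    z <- .addRowVec(cbind(x, h) %*% W, b)
    i <- .sigmoid(z[, idxI, drop = FALSE])
    f <- .sigmoid(z[, idxF, drop = FALSE])
    g <- tanh(z[, idxG, drop = FALSE])
    o <- .sigmoid(z[, idxO, drop = FALSE])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    Hs[, t, ] <- h; Cs[, t, ] <- cc
    Is[, t, ] <- i; Fs[, t, ] <- f; Gs[, t, ] <- g; Os[, t, ] <- o
  }
  list(Hs = Hs, Cs = Cs, Is = Is, Fs = Fs, Gs = Gs, Os = Os)
}

.lstmBackward <- function(dHs, Xs, cache, W, H) {
  d <- dim(Xs); B <- d[1L]; T <- d[2L]; Fin <- d[3L]
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(ncol(W))
  dXs <- array(0, c(B, T, Fin))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(T))) {
    i <- array(cache$Is[, t, ], c(B, H))
    f <- array(cache$Fs[, t, ], c(B, H))
    g <- array(cache$Gs[, t, ], c(B, H))
    o <- array(cache$Os[, t, ], c(B, H))
    cc <- array(cache$Cs[, t, ], c(B, H))
    tc <- tanh(cc)
    dht <- array(dHs[, t, ], c(B, H)) + dh
    do <- dht * tc
    dct <- dc + dht * o * (1 - tc^2)
    cprev <- if (t > 1L) array(cache$Cs[, t - 1L, ], c(B, H))
             else matrix(0, B, H)
    di <- dct * g; dg <- dct * i; df <- dct * cprev
    dc <- dct * f
    dz <- cbind(di * i * (1 - i), df * f * (1 - f), dg * (1 - g^2),
                do * o * (1 - o))
    x <- array(Xs[, t, ], c(B, Fin))
    hprev <- if (t > 1L) array(cache$Hs[, t - 1L, ], c(B, H))
             else matrix(0, B, H)
    xin <- cbind(x, hprev)
    dW <- dW + crossprod(xin, dz)
    db <- db + colSums(dz)
    dxh <- tcrossprod(dz, W)
    dXs[, t, ] <- dxh[, seq_len(Fin), drop = FALSE]
    dh <- dxh[, Fin + seq_len(H), drop = FALSE]
  }
  list(dXs = dXs, dW = dW, db = db)
}

# ---- scaled dot-product self-attention --------------------------------------

.attentionForward <- function(S) {
  d <- dim(S); B <- d[1L]; T <- d[2L]; H <- d[3L]
  A <- array(0, c(B, T, T)); Ctx <- array(0, c(B, T, H))
  sc <- 1 / sqrt(H)
  for (bi in seq_len(B)) {
    Sb <- array(S[bi, , ], c(T, H))
    sco <- tcrossprod(Sb) * sc
    e <- exp(sco - apply(sco, 1L, max))
    Ab <- e / rowSums(e)
    A[bi, , ] <- Ab
    Ctx[bi, , ] <- Ab %*% Sb
  }
  list(A = A, Ctx = Ctx)
}

.attentionBackward <- function(dCtx, S, A) {
  d <- dim(S); B <- d[1L]; T <- d[2L]; H <- d[3L]
  sc <- 1 / sqrt(H)
  dS <- array(0, c(B, T, H))
  for (bi in seq_len(B)) {
    Sb <- array(S[bi, , ], c(T, H))
    Ab <- array(A[bi, , ], c(T, T))
    dCb <- array(dCtx[bi, , ], c(T, H))
    dA <- tcrossprod(dCb, Sb)
    dSb <- crossprod(Ab, dCb)
    dSco <- Ab * (dA - rowSums(dA * Ab))
    dSb <- dSb + (dSco + t(dSco)) %*% Sb * sc
    dS[bi, , ] <- dSb
  }
  dS
}

# ---- full network -----------------------------------------------------------

.nnForward <- function(params, X, cfg, training = FALSE, keepCache = FALSE) {
  c1 <- .convForward(X, params$Wc1, params$bc1, cfg$convKernels[1L])
  p1 <- .poolForward(c1$A, cfg$poolSizes[1L])
  c2 <- .convForward(p1$P, params$Wc2, params$bc2, cfg$convKernels[2L])
  p2 <- .poolForward(c2$A, cfg$poolSizes[2L])
  Z <- p2$P
  drop <- NULL
  if (training && cfg$dropout > 0) {
    keep <- 1 - cfg$dropout
    drop <- array((stats::runif(length(Z)) < keep) / keep, dim(Z))
    Z <- Z * drop
  }
  ls <- .lstmForward(Z, params$Wl, params$bl, cfg$lstmUnits)
  at <- .attentionForward(ls$Hs)
  T3 <- dim(ls$Hs)[2L]
  G <- apply(at$Ctx, c(1L, 3L), mean)
  if (is.null(dim(G))) G <- matrix(G, nrow = dim(X)[1L])
  D1z <- .addRowVec(G %*% params$Wd1, params$bd1)
  D1 <- pmax(D1z, 0)
  logits <- .addRowVec(D1 %*% params$Wd2, params$bd2)
  P <- .softmax(logits)
  out <- list(P = P, logits = logits, attn = at$A)
  if (keepCache)
    out$cache <- list(X = X, c1 = c1, p1 = p1, c2 = c2, p2 = p2,
                      Z = Z, drop = drop, ls = ls, at = at, G = G,
                      D1 = D1, D1z = D1z, P = P, T3 = T3)
  out
}

.nnLoss <- function(P, y) {
  -mean(log(P[cbind(seq_along(y), y + 1L)] + 1e-12))
}

.nnBackward <- function(params, cfg, cache, y) {
  B <- nrow(cache$P)
  Y1 <- matrix(0, B, 2L)
  Y1[cbind(seq_len(B), y + 1L)] <- 1
  dLogits <- (cache$P - Y1) / B
  dWd2 <- crossprod(cache$D1, dLogits)
  dbd2 <- colSums(dLogits)
  dD1 <- tcrossprod(dLogits, params$Wd2) * (cache$D1z > 0)
  dWd1 <- crossprod(cache$G, dD1)
  dbd1 <- colSums(dD1)
  dG <- tcrossprod(dD1, params$Wd1)
  T3 <- cache$T3
  H <- cfg$lstmUnits
  dCtx <- aperm(array(dG / T3, c(B, H, T3)), c(1L, 3L, 2L))
  dHs <- .attentionBackward(dCtx, cache$ls$Hs, cache$at$A)
  lb <- .lstmBackward(dHs, cache$Z, cache$ls, params$Wl, H)
  dZ <- lb$dXs
  if (!is.null(cache$drop)) dZ <- dZ * cache$drop
  dA2 <- .poolBackward(dZ, cache$p2)
  cb2 <- .convBackward(dA2, cache$c2, params$Wc2)
  dA1 <- .poolBackward(cb2$dX, cache$p1)
  cb1 <- .convBackward(dA1, cache$c1, params$Wc1)
  list(Wc1 = cb1$dW, bc1 = cb1$db, Wc2 = cb2$dW, bc2 = cb2$db,
       Wl = lb$dW, bl = lb$db, Wd1 = dWd1, bd1 = dbd1,
       Wd2 = dWd2, bd2 = dbd2)
}

# ---- Adam -------------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / b1t) / (sqrt(state$v[[nm]] / b2t) + eps)
  }
  list(params = params, state = state)
}

# Evaluate loss/accuracy over a set in eval mode, batched.
.nnEvaluate <- function(params, X, y, cfg, batch = 64L) {
  n <- dim(X)[1L]
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = batch)) {
    e <- min(s + batch - 1L, n)
    out <- .nnForward(params, X[s:e, , , drop = FALSE], cfg)
    yi <- y[s:e]
    loss <- loss + .nnLoss(out$P, yi) * (e - s + 1L)
    correct <- correct + sum(max.col(out$P, ties.method = "first") == yi + 1L)
  }
  list(loss = loss / n, acc = correct / n)
}
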
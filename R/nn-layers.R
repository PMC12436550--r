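# Hand-built neural-network layers: forward passes, caches, and exact
# backward passes, all in base R matrix code over BLAS. Convolutions are
# im2col + matrix multiply; attention loops over (sample, head) pairs, which
# at this package's problem sizes is dominated by the BLAS calls anyway.
# Gradient correctness is pinned down by finite-difference tests.

# ---- initializers ---------------------------------------------------------

he_mat <- function(nout, nin) {
  matrix(stats::rnorm(nout * nin, sd = sqrt(2 / nin)), nout, nin)
}

glorot_mat <- function(nout, nin) {
  s <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nout * nin, -s, s), nout, nin)
}

# ---- elementwise ----------------------------------------------------------

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

relu_bwd <- function(cache, dout) dout * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense ----------------------------------------------------------------

# X: (nin, M) column-per-example; W: (nout, nin)
linear_fwd <- function(W, b, X) W %*% X + b

linear_bwd <- function(W, X, dY) {
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

# ---- 1-D convolution over time, shared across sequences -------------------

# A: (Fin, N, L) with time as the trailing (contiguous-range) axis;
# W: (Fout, Fin * k), column block j holding the kernel tap at offset j.
# Valid convolution, stride 1, computed as k shifted GEMMs — no im2col
# patch matrix is materialized.
conv1d_fwd <- function(W, b, A, k) {
  d <- dim(A); Fin <- d[1L]; N <- d[2L]; Lin <- d[3L]
  Lout <- Lin - k + 1L
  if (Lout < 1L) stop("sequence too short for kernel size ", k)
  Am <- A; dim(Am) <- c(Fin, N * Lin)
  Y <- matrix(b, nrow(W), N * Lout)
  for (j in seq_len(k)) {
    # columns of Am holding time steps j .. j+Lout-1: one contiguous range
    cols <- ((j - 1L) * N + 1L):((j + Lout - 1L) * N)
    Y <- Y + W[, ((j - 1L) * Fin + 1L):(j * Fin), drop = FALSE] %*%
      Am[, cols, drop = FALSE]
  }
  dim(Y) <- c(nrow(W), N, Lout)
  list(out = Y, Am = Am, dims = c(Fin, Lin, N, Lout, k))
}

conv1d_bwd <- function(W, cache, dY, want_dA = TRUE) {
  d <- cache$dims; Fin <- d[1L]; Lin <- d[2L]; N <- d[3L]
  Lout <- d[4L]; k <- d[5L]
  K <- nrow(W)
  dYm <- dY; dim(dYm) <- c(K, N * Lout)
  db <- rowSums(dYm)
  dW <- matrix(0, K, Fin * k)
  dAm <- if (want_dA) matrix(0, Fin, N * Lin) else NULL
  for (j in seq_len(k)) {
    cols <- ((j - 1L) * N + 1L):((j + Lout - 1L) * N)
    wcols <- ((j - 1L) * Fin + 1L):(j * Fin)
    dW[, wcols] <- tcrossprod(dYm, cache$Am[, cols, drop = FALSE])
    if (want_dA)
      dAm[, cols] <- dAm[, cols, drop = FALSE] +
        crossprod(W[, wcols, drop = FALSE], dYm)
  }
  if (want_dA) dim(dAm) <- c(Fin, N, Lin)
  list(dA = dAm, dW = dW, db = db)
}

# Max-pool by 2 along the trailing time axis of an (F, N, L) array. A
# trailing odd sample is dropped, as in floor pooling. Ties take the earlier
# sample.
pool1d_fwd <- function(A) {
  d <- dim(A); N <- d[2L]; L <- d[3L]; Lp <- L %/% 2L
  c1 <- rep((seq.int(1L, 2L * Lp, 2L) - 1L) * N, each = N) + seq_len(N)
  Am <- A; dim(Am) <- c(d[1L], N * L)
  A1 <- Am[, c1, drop = FALSE]
  A2 <- Am[, c1 + N, drop = FALSE]
  m <- A1 >= A2
  out <- pmax(A1, A2)
  dim(out) <- c(d[1L], N, Lp)
  list(out = out, mask = m, c1 = c1, dims = d)
}

pool1d_bwd <- function(cache, dY) {
  d <- cache$dims
  dim(dY) <- dim(cache$mask)
  dAm <- matrix(0, d[1L], d[2L] * d[3L])
  dAm[, cache$c1] <- dY * cache$mask
  dAm[, cache$c1 + d[2L]] <- dY * !cache$mask
  dim(dAm) <- d
  dAm
}

# ---- 2-D convolution over (channel, time) ---------------------------------

# A: (Fin, Cin, Lin, N); kernel kc x kl (kc = 1 when the channel axis is not
# reduced in this block); W: (Fout, Fin * kc * kl).
conv2d_fwd <- function(W, b, A, kc, kl) {
  d <- dim(A); Fin <- d[1L]; Cin <- d[2L]; Lin <- d[3L]; N <- d[4L]
  Cout <- Cin - kc + 1L; Lout <- Lin - kl + 1L
  if (Cout < 1L || Lout < 1L) stop("input too small for ", kc, "x", kl,
                                   " kernel")
  P <- array(0, dim = c(Fin * kc * kl, Cout, Lout, N))
  j <- 0L
  for (dl in seq_len(kl)) for (dc in seq_len(kc)) {
    j <- j + 1L
    P[((j - 1L) * Fin + 1L):(j * Fin), , , ] <-
      A[, dc:(dc + Cout - 1L), dl:(dl + Lout - 1L), , drop = FALSE]
  }
  dim(P) <- c(Fin * kc * kl, Cout * Lout * N)
  Y <- W %*% P + b
  dim(Y) <- c(nrow(W), Cout, Lout, N)
  list(out = Y, P = P, dims = c(Fin, Cin, Lin, N, Cout, Lout, kc, kl))
}

conv2d_bwd <- function(W, cache, dY, want_dA = TRUE) {
  d <- cache$dims
  Fin <- d[1L]; Cin <- d[2L]; Lin <- d[3L]; N <- d[4L]
  Cout <- d[5L]; Lout <- d[6L]; kc <- d[7L]; kl <- d[8L]
  dim(dY) <- c(nrow(W), Cout * Lout * N)
  dW <- tcrossprod(dY, cache$P)
  db <- rowSums(dY)
  dA <- NULL
  if (want_dA) {
    dP <- crossprod(W, dY)
    dim(dP) <- c(Fin * kc * kl, Cout, Lout, N)
    dA <- array(0, dim = c(Fin, Cin, Lin, N))
    j <- 0L
    for (dl in seq_len(kl)) for (dc in seq_len(kc)) {
      j <- j + 1L
      dA[, dc:(dc + Cout - 1L), dl:(dl + Lout - 1L), ] <-
        dA[, dc:(dc + Cout - 1L), dl:(dl + Lout - 1L), , drop = FALSE] +
        dP[((j - 1L) * Fin + 1L):(j * Fin), , , , drop = FALSE]
    }
  }
  list(dA = dA, dW = dW, db = db)
}

# Max-pool by 2 along one axis (2 = channel, 3 = time) of an (F,C,L,N) array.
pool2d_fwd <- function(A, axis) {
  d <- dim(A); n <- d[axis]; np <- n %/% 2L
  i1 <- seq.int(1L, 2L * np, 2L)
  if (axis == 2L) {
    A1 <- A[, i1, , , drop = FALSE]; A2 <- A[, i1 + 1L, , , drop = FALSE]
  } else {
    A1 <- A[, , i1, , drop = FALSE]; A2 <- A[, , i1 + 1L, , drop = FALSE]
  }
  m <- A1 >= A2
  list(out = pmax(A1, A2), mask = m, dims = d, axis = axis)
}

pool2d_bwd <- function(cache, dY) {
  d <- cache$dims; axis <- cache$axis; np <- d[axis] %/% 2L
  i1 <- seq.int(1L, 2L * np, 2L)
  dA <- array(0, dim = d)
  if (axis == 2L) {
    dA[, i1, , ] <- dY * cache$mask
    dA[, i1 + 1L, , ] <- dY * !cache$mask
  } else {
    dA[, , i1, ] <- dY * cache$mask
    dA[, , i1 + 1L, ] <- dY * !cache$mask
  }
  dA
}

# ---- layer norm -----------------------------------------------------------

# X: (K, M), normalized per column (per token) over the feature axis.
ln_fwd <- function(g, b, X) {
  mu <- colMeans(X)
  xc <- sweep(X, 2, mu)
  s <- sqrt(colMeans(xc^2) + 1e-6)
  xhat <- sweep(xc, 2, s, "/")
  list(out = xhat * g + b, xhat = xhat, s = s)
}

ln_bwd <- function(g, cache, dY) {
  xhat <- cache$xhat
  K <- nrow(xhat)
  dxhat <- dY * g
  dX <- sweep(dxhat - rep(colMeans(dxhat), each = K) -
                xhat * rep(colMeans(dxhat * xhat), each = K),
              2, cache$s, "/")
  list(dX = dX, dg = rowSums(dY * xhat), db = rowSums(dY))
}

# ---- multi-head self-attention --------------------------------------------

softmax_rows <- function(S) {
  S <- S - apply(S, 1, max)
  E <- exp(S)
  E / rowSums(E)
}

# X: (K, S, B) tokens, features first. p holds Wq, Wk, Wv, Wo (K x K) and
# biases. Returns out (K, S, B) and the head-averaged attention (S, S, B).
mha_fwd <- function(p, X, heads) {
  d <- dim(X); K <- d[1L]; S <- d[2L]; B <- d[3L]
  dh <- K %/% heads
  Xm <- X; dim(Xm) <- c(K, S * B)
  Q <- p$Wq %*% Xm + p$bq; Kk <- p$Wk %*% Xm + p$bk; V <- p$Wv %*% Xm + p$bv
  dim(Q) <- dim(Kk) <- dim(V) <- c(K, S, B)
  O <- array(0, dim = c(K, S, B))
  att <- array(0, dim = c(S, S, heads, B))
  for (b in seq_len(B)) for (h in seq_len(heads)) {
    rh <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- Q[rh, , b]; Kh <- Kk[rh, , b]; Vh <- V[rh, , b]
    if (dh == 1L) { Qh <- rbind(Qh); Kh <- rbind(Kh); Vh <- rbind(Vh) }
    A <- softmax_rows(crossprod(Qh, Kh) / sqrt(dh))
    att[, , h, b] <- A
    O[rh, , b] <- Vh %*% t(A)
  }
  Om <- O; dim(Om) <- c(K, S * B)
  Y <- p$Wo %*% Om + p$bo
  dim(Y) <- c(K, S, B)
  am <- aperm(att, c(1, 2, 4, 3))       # (S, S, B, heads)
  dim(am) <- c(S * S * B, heads)
  att_mean <- array(rowMeans(am), dim = c(S, S, B))
  list(out = Y, att = att, att_mean = att_mean,
       cache = list(X = Xm, Q = Q, K = Kk, V = V, O = O, heads = heads))
}

mha_bwd <- function(p, cache, dY) {
  K <- dim(cache$Q)[1L]; S <- dim(cache$Q)[2L]; B <- dim(cache$Q)[3L]
  heads <- cache$heads; dh <- K %/% heads
  dim(dY) <- c(K, S * B)
  Om <- cache$O; dim(Om) <- c(K, S * B)
  dWo <- tcrossprod(dY, Om); dbo <- rowSums(dY)
  dO <- crossprod(p$Wo, dY)
  dim(dO) <- c(K, S, B)
  dQ <- array(0, dim = c(K, S, B)); dK <- dQ; dV <- dQ
  att <- NULL
  for (b in seq_len(B)) for (h in seq_len(heads)) {
    rh <- ((h - 1L) * dh + 1L):(h * dh)
    Qh <- cache$Q[rh, , b]; Kh <- cache$K[rh, , b]; Vh <- cache$V[rh, , b]
    if (dh == 1L) { Qh <- rbind(Qh); Kh <- rbind(Kh); Vh <- rbind(Vh) }
    A <- softmax_rows(crossprod(Qh, Kh) / sqrt(dh))
    dOh <- dO[rh, , b]
    if (dh == 1L) dOh <- rbind(dOh)
    # O = Vh %*% t(A) => dA[s, j] = sum_d dOh[d, s] * Vh[d, j]
    dA <- crossprod(dOh, Vh)
    dVh <- dOh %*% A
    dS <- A * (dA - rowSums(dA * A))
    dQ[rh, , b] <- Kh %*% t(dS) / sqrt(dh)
    dK[rh, , b] <- Qh %*% dS / sqrt(dh)
    dV[rh, , b] <- dVh
  }
  dim(dQ) <- dim(dK) <- dim(dV) <- c(K, S * B)
  Xm <- cache$X
  grads <- list(
    Wq = tcrossprod(dQ, Xm), bq = rowSums(dQ),
    Wk = tcrossprod(dK, Xm), bk = rowSums(dK),
    Wv = tcrossprod(dV, Xm), bv = rowSums(dV),
    Wo = dWo, bo = dbo)
  dX <- crossprod(p$Wq, dQ) + crossprod(p$Wk, dK) + crossprod(p$Wv, dV)
  dim(dX) <- c(K, S, B)
  list(dX = dX, grads = grads)
}

# ---- transformer encoder layer (post-LN) ----------------------------------

transformer_layer_init <- function(K, ff) {
  list(Wq = glorot_mat(K, K), bq = rep(0, K),
       Wk = glorot_mat(K, K), bk = rep(0, K),
       Wv = glorot_mat(K, K), bv = rep(0, K),
       Wo = glorot_mat(K, K), bo = rep(0, K),
       g1 = rep(1, K), c1 = rep(0, K),
       W1 = he_mat(ff, K), b1 = rep(0, ff),
       W2 = glorot_mat(K, ff), b2 = rep(0, K),
       g2 = rep(1, K), c2 = rep(0, K))
}

transformer_layer_fwd <- function(p, X, heads) {
  d <- dim(X); K <- d[1L]; S <- d[2L]; B <- d[3L]
  mh <- mha_fwd(p, X, heads)
  R1 <- X + mh$out
  dim(R1) <- c(K, S * B)
  l1 <- ln_fwd(p$g1, p$c1, R1)
  H1 <- linear_fwd(p$W1, p$b1, l1$out)
  r1 <- relu_fwd(H1)
  FF <- linear_fwd(p$W2, p$b2, r1$out)
  R2 <- l1$out + FF
  l2 <- ln_fwd(p$g2, p$c2, R2)
  out <- l2$out
  dim(out) <- c(K, S, B)
  list(out = out, att_mean = mh$att_mean,
       cache = list(mh = mh$cache, l1 = l1, r1 = r1, l2 = l2,
                    L1out = l1$out, H1in = H1, dims = d))
}

transformer_layer_bwd <- function(p, cache, dOut) {
  d <- cache$dims; K <- d[1L]; S <- d[2L]; B <- d[3L]
  dim(dOut) <- c(K, S * B)
  b2w <- ln_bwd(p$g2, cache$l2, dOut)
  dR2 <- b2w$dX
  ff2 <- linear_bwd(p$W2, cache$r1$out, dR2)
  dH1 <- relu_bwd(cache$r1, ff2$dX)
  ff1 <- linear_bwd(p$W1, cache$L1out, dH1)
  dL1 <- dR2 + ff1$dX
  b1w <- ln_bwd(p$g1, cache$l1, dL1)
  dR1 <- b1w$dX
  dim(dR1) <- c(K, S, B)
  mhb <- mha_bwd(p, cache$mh, dR1)
  dX <- dR1 + mhb$dX
  grads <- c(mhb$grads,
             list(g1 = b1w$dg, c1 = b1w$db,
                  W1 = ff1$dW, b1 = ff1$db,
                  W2 = ff2$dW, b2 = ff2$db,
                  g2 = b2w$dg, c2 = b2w$db))
  list(dX = dX, grads = grads)
}

# ---- LSTM -----------------------------------------------------------------

lstm_init <- function(D, H) {
  W <- rbind(glorot_mat(H, D + H), glorot_mat(H, D + H),
             glorot_mat(H, D + H), glorot_mat(H, D + H))
  b <- rep(0, 4 * H)
  b[(H + 1):(2 * H)] <- 1  # forget-gate bias
  list(Wx = W[, seq_len(D), drop = FALSE],
       Wh = W[, D + seq_len(H), drop = FALSE], b = b)
}

# xs: list of T matrices (D, B). Returns the final hidden state (H, B).
lstm_fwd <- function(p, xs) {
  H <- nrow(p$Wh) %/% 4L
  B <- ncol(xs[[1L]])
  h <- matrix(0, H, B); c <- matrix(0, H, B)
  steps <- vector("list", length(xs))
  ri <- seq_len(H); rf <- H + ri; rg <- 2L * H + ri; ro <- 3L * H + ri
  for (t in seq_along(xs)) {
    Z <- p$Wx %*% xs[[t]] + p$Wh %*% h + p$b
    i <- sigmoid(Z[ri, , drop = FALSE]); f <- sigmoid(Z[rf, , drop = FALSE])
    g <- tanh(Z[rg, , drop = FALSE]); o <- sigmoid(Z[ro, , drop = FALSE])
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    steps[[t]] <- list(x = xs[[t]], h_prev = h, c_prev = c,
                       i = i, f = f, g = g, o = o, tc = tc)
    c <- c_new
    h <- o * tc
  }
  list(h = h, cache = steps)
}

lstm_bwd <- function(p, cache, dh_last) {
  H <- nrow(p$Wh) %/% 4L
  Tn <- length(cache)
  dWx <- p$Wx * 0; dWh <- p$Wh * 0; db <- p$b * 0
  dh <- dh_last
  dc <- dh * 0
  dxs <- vector("list", Tn)
  for (t in rev(seq_len(Tn))) {
    s <- cache[[t]]
    do <- dh * s$tc
    dc <- dc + dh * s$o * (1 - s$tc^2)
    di <- dc * s$g; df <- dc * s$c_prev; dg <- dc * s$i
    dc_prev <- dc * s$f
    dZ <- rbind(di * s$i * (1 - s$i), df * s$f * (1 - s$f),
                dg * (1 - s$g^2), do * s$o * (1 - s$o))
    dWx <- dWx + tcrossprod(dZ, s$x)
    dWh <- dWh + tcrossprod(dZ, s$h_prev)
    db <- db + rowSums(dZ)
    dxs[[t]] <- crossprod(p$Wx, dZ)
    dh <- crossprod(p$Wh, dZ)
    dc <- dc_prev
  }
  list(dxs = dxs, dWx = dWx, dWh = dWh, db = db)
}
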
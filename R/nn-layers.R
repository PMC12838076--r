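# Reverse-mode layer primitives for the 1D ResNet-Transformer model.
# Tensors are base-R arrays with dim c(batch, length, channels); reshaping
# between (B, L, C) arrays and (B*L, C) matrices is free because the first
# two dimensions are adjacent in column-major order.

as_mat <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

as_arr <- function(x, d) {
  dim(x) <- d
  x
}

conv1d_forward <- function(x, W, b, stride = 1L, pad = 0L) {
  d <- dim(x)
  B <- d[1]; Lin <- d[2]; Cin <- d[3]
  K <- dim(W)[1]; Cout <- dim(W)[3]
  Lp <- Lin + 2L * pad
  if (pad > 0) {
    xp <- array(0, c(B, Lp, Cin))
    xp[, pad + seq_len(Lin), ] <- x
  } else {
    xp <- x
  }
  Lout <- (Lp - K) %/% stride + 1L
  if (Lout < 1) stop("conv1d: input length ", Lin, " too short for kernel ", K)
  outm <- matrix(b, B * Lout, Cout, byrow = TRUE)
  for (k in seq_len(K)) {
    idx <- seq.int(k, by = stride, length.out = Lout)
    Mk <- xp[, idx, , drop = FALSE]
    dim(Mk) <- c(B * Lout, Cin)
    outm <- outm + Mk %*% matrix(W[k, , ], Cin, Cout)
  }
  list(out = as_arr(outm, c(B, Lout, Cout)),
       cache = list(xp = xp, stride = stride, pad = pad,
                    Lin = Lin, Lout = Lout, K = K))
}

conv1d_backward <- function(dout, W, cache) {
  xp <- cache$xp
  d <- dim(xp)
  B <- d[1]; Lp <- d[2]; Cin <- d[3]
  K <- cache$K; Lout <- cache$Lout; Cout <- dim(W)[3]
  G <- as_mat(dout)
  db <- colSums(G)
  dW <- array(0, dim(W))
  dxp <- array(0, c(B, Lp, Cin))
  for (k in seq_len(K)) {
    idx <- seq.int(k, by = cache$stride, length.out = Lout)
    Mk <- xp[, idx, , drop = FALSE]
    dim(Mk) <- c(B * Lout, Cin)
    dW[k, , ] <- crossprod(Mk, G)
    dXk <- G %*% t(matrix(W[k, , ], Cin, Cout))
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + as_arr(dXk, c(B, Lout, Cin))
  }
  dx <- if (cache$pad > 0) {
    dxp[, cache$pad + seq_len(cache$Lin), , drop = FALSE]
  } else {
    dxp
  }
  list(dx = dx, dW = dW, db = db)
}

# Per-sample instance normalization with per-channel scale/shift: each
# (sample, channel) trace is standardized over its temporal axis. Unlike
# batch normalization, the output is independent of minibatch composition,
# which keeps features stable with the small batches used on a CPU; the
# reference architecture leaves the normalization layer unspecified. The
# `state`/`training` arguments are retained for interface stability but the
# computation is identical in both modes.
bn_forward <- function(x, gamma, beta, state, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x)  # (B, L, C)
  B <- d[1]; L <- d[2]; C <- d[3]
  xp <- aperm(x, c(2, 1, 3))
  dim(xp) <- c(L, B * C)
  mu <- colMeans(xp)
  xc <- sweep(xp, 2, mu)
  v <- colMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2, invstd, `*`)
  chan <- rep(seq_len(C), each = B)
  y <- sweep(sweep(xhat, 2, gamma[chan], `*`), 2, beta[chan], `+`)
  dim(y) <- c(L, B, C)
  list(out = aperm(y, c(2, 1, 3)), state = state,
       cache = list(xhat = xhat, invstd = invstd, d = d, chan = chan))
}

bn_backward <- function(dout, gamma, cache) {
  d <- cache$d
  B <- d[1]; L <- d[2]; C <- d[3]
  G <- aperm(dout, c(2, 1, 3))
  dim(G) <- c(L, B * C)
  xhat <- cache$xhat
  chan <- cache$chan
  gx <- colSums(G * xhat)
  gs <- colSums(G)
  dgamma <- as.numeric(rowsum(gx, chan))
  dbeta <- as.numeric(rowsum(gs, chan))
  dxhat <- sweep(G, 2, gamma[chan], `*`)
  t1 <- sweep(dxhat, 2, colMeans(dxhat))
  t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), `*`)
  dx <- sweep(t1 - t2, 2, cache$invstd, `*`)
  dim(dx) <- c(L, B, C)
  list(dx = aperm(dx, c(2, 1, 3)), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, cache = mask)
}

relu_backward <- function(dout, mask) {
  dout[!mask] <- 0
  dout
}

maxpool_forward <- function(x, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(x)
  B <- d[1]; Lin <- d[2]; C <- d[3]
  Lp <- Lin + 2L * pad
  xp <- array(-Inf, c(B, Lp, C))
  xp[, pad + seq_len(Lin), ] <- x
  Lout <- (Lp - k) %/% stride + 1L
  out <- array(-Inf, c(B, Lout, C))
  arg <- array(1L, c(B, Lout, C))
  for (j in seq_len(k)) {
    idx <- seq.int(j, by = stride, length.out = Lout)
    cand <- xp[, idx, , drop = FALSE]
    better <- cand > out
    out[better] <- cand[better]
    arg[better] <- j
  }
  list(out = out,
       cache = list(arg = arg, d = d, k = k, stride = stride, pad = pad,
                    Lp = Lp, Lout = Lout))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$d
  dxp <- array(0, c(d[1], cache$Lp, d[3]))
  zero <- array(0, dim(dout))
  for (j in seq_len(cache$k)) {
    idx <- seq.int(j, by = cache$stride, length.out = cache$Lout)
    contrib <- zero
    sel <- cache$arg == j
    contrib[sel] <- dout[sel]
    dxp[, idx, ] <- dxp[, idx, , drop = FALSE] + contrib
  }
  dxp[, cache$pad + seq_len(d[2]), , drop = FALSE]
}

linear_forward <- function(x, W, b) {
  list(out = sweep(x %*% W, 2, b, `+`), cache = x)
}

linear_backward <- function(dout, W, cache) {
  list(dx = dout %*% t(W), dW = crossprod(cache, dout), db = colSums(dout))
}

ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  xm <- as_mat(x)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc^2)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * invstd
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = as_arr(y, d),
       cache = list(xhat = xhat, invstd = invstd, d = d))
}

ln_backward <- function(dout, gamma, cache) {
  d <- cache$d
  G <- as_mat(dout)
  xhat <- cache$xhat
  dgamma <- colSums(G * xhat)
  dbeta <- colSums(G)
  dxhat <- sweep(G, 2, gamma, `*`)
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$invstd
  list(dx = as_arr(dx, d), dgamma = dgamma, dbeta = dbeta)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Multi-head self-attention over tokens (B, T, D), post-projection output.
mha_forward <- function(x, p, n_heads) {
  d <- dim(x)
  B <- d[1]; Tn <- d[2]; D <- d[3]
  dh <- D %/% n_heads
  xm <- as_mat(x)
  Q <- sweep(xm %*% p$Wq, 2, p$bq, `+`)
  K <- sweep(xm %*% p$Wk, 2, p$bk, `+`)
  V <- sweep(xm %*% p$Wv, 2, p$bv, `+`)
  H <- matrix(0, B * Tn, D)
  attn <- vector("list", B * n_heads)
  rows_of <- function(b) seq.int(b, by = B, length.out = Tn)
  for (b in seq_len(B)) {
    rws <- rows_of(b)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      Qbh <- Q[rws, cols, drop = FALSE]
      Kbh <- K[rws, cols, drop = FALSE]
      Vbh <- V[rws, cols, drop = FALSE]
      S <- tcrossprod(Qbh, Kbh) / sqrt(dh)
      A <- softmax_rows(S)
      H[rws, cols] <- A %*% Vbh
      attn[[(b - 1) * n_heads + h]] <- A
    }
  }
  out <- sweep(H %*% p$Wo, 2, p$bo, `+`)
  list(out = as_arr(out, d),
       cache = list(xm = xm, Q = Q, K = K, V = V, H = H, attn = attn,
                    d = d, n_heads = n_heads, dh = dh))
}

mha_backward <- function(dout, p, cache) {
  d <- cache$d
  B <- d[1]; Tn <- d[2]; D <- d[3]
  n_heads <- cache$n_heads
  dh <- cache$dh
  G <- as_mat(dout)
  dWo <- crossprod(cache$H, G)
  dbo <- colSums(G)
  dH <- G %*% t(p$Wo)
  dQ <- matrix(0, B * Tn, D)
  dK <- matrix(0, B * Tn, D)
  dV <- matrix(0, B * Tn, D)
  for (b in seq_len(B)) {
    rws <- seq.int(b, by = B, length.out = Tn)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * dh + 1):(h * dh)
      A <- cache$attn[[(b - 1) * n_heads + h]]
      Qbh <- cache$Q[rws, cols, drop = FALSE]
      Kbh <- cache$K[rws, cols, drop = FALSE]
      Vbh <- cache$V[rws, cols, drop = FALSE]
      dHbh <- dH[rws, cols, drop = FALSE]
      dA <- tcrossprod(dHbh, Vbh)
      dV[rws, cols] <- crossprod(A, dHbh)
      dS <- A * (dA - rowSums(dA * A))
      dS <- dS / sqrt(dh)
      dQ[rws, cols] <- dS %*% Kbh
      dK[rws, cols] <- crossprod(dS, Qbh)
    }
  }
  dWq <- crossprod(cache$xm, dQ)
  dWk <- crossprod(cache$xm, dK)
  dWv <- crossprod(cache$xm, dV)
  dxm <- dQ %*% t(p$Wq) + dK %*% t(p$Wk) + dV %*% t(p$Wv)
  list(dx = as_arr(dxm, d),
       grads = list(Wq = dWq, bq = colSums(dQ), Wk = dWk, bk = colSums(dK),
                    Wv = dWv, bv = colSums(dV), Wo = dWo, bo = dbo))
}

# Elementwise tree utilities over nested parameter lists.
# Trees are matched by name where names exist (gradient trees may list the
# same components in a different order than the parameter tree).
tree_map <- function(f, ...) {
  trees <- list(...)
  a <- trees[[1]]
  if (is.null(a)) return(NULL)
  if (is.list(a)) {
    keys <- names(a)
    if (is.null(keys)) {
      out <- lapply(seq_along(a), function(i) {
        do.call(tree_map, c(list(f), lapply(trees, `[[`, i)))
      })
    } else {
      out <- lapply(keys, function(k) {
        do.call(tree_map, c(list(f), lapply(trees, `[[`, k)))
      })
      names(out) <- keys
    }
    out
  } else {
    do.call(f, trees)
  }
}

tree_sum <- function(tree, f = identity) {
  if (is.null(tree)) return(0)
  if (is.list(tree)) return(sum(vapply(tree, tree_sum, numeric(1), f = f)))
  sum(f(tree))
}
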
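# Low-level 1D neural-network primitives.
#
# All activations are 3D arrays [N, L, C] (batch, time, channels). Heavy
# lifting is delegated to BLAS through im2col + matrix multiplication.
# Weight arrays for convolutions are [C_in, k, C_out]: flattened
# column-major this gives rows indexed input-channel-fastest within each
# kernel tap, matching the contiguous per-tap channel blocks of the
# im2col matrix built below.

conv1d_forward <- function(X, W, stride = 1L, pad = 0L) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[2]; Cout <- dim(W)[3]
  Wm <- W; dim(Wm) <- c(k * C, Cout)
  r <- conv1d_fwd_cpp(X, Wm, k, stride, pad)
  Y <- r$Y
  dim(Y) <- c(N, r$Lout, Cout)
  list(Y = Y, cache = list(Xcol = r$Xcol, dimW = dim(W), N = N, L = L,
                           C = C, Lout = r$Lout, stride = stride,
                           pad = pad))
}

conv1d_backward <- function(dY, W, cache, need_dx = TRUE) {
  k <- cache$dimW[2]; C <- cache$dimW[1]; Cout <- cache$dimW[3]
  N <- cache$N; Lout <- cache$Lout
  dYm <- dY; dim(dYm) <- c(N * Lout, Cout)
  Wm <- W; dim(Wm) <- c(k * C, Cout)
  r <- conv1d_bwd_cpp(dYm, cache$Xcol, Wm, N, cache$L, C, k,
                      cache$stride, cache$pad, need_dx)
  dW <- r$dW
  dim(dW) <- cache$dimW
  list(dX = r$dX, dW = dW)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

# column-wise scale/shift without sweep() (which is aperm-heavy);
# rep.int with a times-vector is the fastest recycling primitive
col_recycle <- function(v, m) rep.int(v, rep.int(m, length(v)))

bn_forward <- function(X, gamma, beta, run_mean, run_var, training) {
  d <- dim(X); C <- d[3]; M <- prod(d[1:2])
  Xm <- X; dim(Xm) <- c(M, C)
  if (training) {
    mu <- colMeans(Xm)
    v <- colMeans(Xm * Xm) - mu * mu
    v[v < 0] <- 0
    new_mean <- BN_MOMENTUM * run_mean + (1 - BN_MOMENTUM) * mu
    new_var <- BN_MOMENTUM * run_var + (1 - BN_MOMENTUM) * v
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- (Xm - col_recycle(mu, M)) * col_recycle(invstd, M)
  Y <- xhat * col_recycle(gamma, M) + col_recycle(beta, M)
  dim(Y) <- d
  list(Y = Y,
       cache = list(xhat = xhat, invstd = invstd, dims = d,
                    training = training),
       run_mean = new_mean, run_var = new_var)
}

bn_backward <- function(dY, gamma, cache) {
  d <- cache$dims; C <- d[3]; M <- prod(d[1:2])
  dYm <- dY; dim(dYm) <- c(M, C)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  dxhat <- dYm * col_recycle(gamma, M)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dXm <- (dxhat - col_recycle(s1 / M, M) -
              cache$xhat * col_recycle(s2 / M, M)) *
      col_recycle(cache$invstd, M)
  } else {
    dXm <- dxhat * col_recycle(cache$invstd, M)
  }
  dim(dXm) <- d
  list(dX = dXm, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(X) {
  mask <- X > 0
  list(Y = X * mask, cache = mask)
}

relu_backward <- function(dY, mask) dY * mask

maxpool_forward <- function(X, k = 3L, stride = 2L, pad = 1L) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  Lout <- (L + 2L * pad - k) %/% stride + 1L
  Xp <- array(-Inf, c(N, L + 2L * pad, C))
  Xp[, (pad + 1L):(pad + L), ] <- X
  Y <- array(-Inf, c(N, Lout, C))
  arg <- array(1L, c(N, Lout, C))
  for (t in seq_len(k)) {
    idx <- seq.int(t, by = stride, length.out = Lout)
    cand <- Xp[, idx, , drop = FALSE]
    better <- cand > Y
    Y[better] <- cand[better]
    arg[better] <- t
  }
  list(Y = Y, cache = list(arg = arg, N = N, L = L, C = C, Lout = Lout,
                           k = k, stride = stride, pad = pad))
}

maxpool_backward <- function(dY, cache) {
  N <- cache$N; L <- cache$L; C <- cache$C
  pad <- cache$pad; k <- cache$k; stride <- cache$stride
  dXp <- array(0, c(N, L + 2L * pad, C))
  for (t in seq_len(k)) {
    idx <- seq.int(t, by = stride, length.out = cache$Lout)
    dXp[, idx, ] <- dXp[, idx, , drop = FALSE] + dY * (cache$arg == t)
  }
  dXp[, (pad + 1L):(pad + L), , drop = FALSE]
}

gap_forward <- function(X) {
  d <- dim(X); N <- d[1]; L <- d[2]; C <- d[3]
  Y <- matrix(0, N, C)
  for (cc in seq_len(C)) {
    Xc <- X[, , cc, drop = FALSE]
    dim(Xc) <- c(N, L)
    Y[, cc] <- rowMeans(Xc)
  }
  list(Y = Y, cache = d)
}

gap_backward <- function(dY, dims) {
  N <- dims[1]; L <- dims[2]; C <- dims[3]
  dX <- array(0, c(N, L, C))
  scale <- dY / L
  for (cc in seq_len(C)) dX[, , cc] <- scale[, cc]  # recycled over time
  dX
}

dense_forward <- function(X, W, b) {
  list(Y = X %*% W + col_recycle(b, nrow(X)), cache = X)
}

dense_backward <- function(dY, W, cache) {
  list(dX = tcrossprod(dY, W), dW = crossprod(cache, dY), db = colSums(dY))
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

he_conv <- function(k, cin, cout) {
  array(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
        c(cin, k, cout))
}

he_dense <- function(cin, cout) {
  matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout)
}
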
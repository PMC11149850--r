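# Low-level neural-network operations for variable-length 1-D signals.
#
# A batch of B waveforms at padded length L with C channels is stored
# channel-major as a C x N matrix with column n = (b-1)*L + t. This layout
# makes the convolution gathers/scatters contiguous column operations and
# lets per-channel affine parameters broadcast by plain vector recycling
# (v * X with length(v) == nrow(X)), both of which dominate the run time
# in R at these shapes.
#
# Each sample carries its own valid length; every operation zeroes the
# columns beyond a sample's valid length so that values in the padded
# region are exactly 0 throughout the network. Under that convention a
# "same"-padded convolution at a valid position sees exactly what it would
# see if the sample were processed alone, which makes embeddings invariant
# to the amount of right-padding.

# numeric position mask (1 valid / 0 padded) for lengths at padded length L
nn_valid_mask <- function(lengths, L) {
  as.numeric(rep(lengths, each = L) >= rep.int(seq_len(L), length(lengths)))
}

# expand a per-position mask to all channels (C x N multiply mask)
nn_cmask <- function(valid, C) rep(valid, each = C)

# valid length after a same-padded conv of kernel k, stride s
nn_out_len <- function(lv, k, s) {
  p <- (k - 1L) %/% 2L
  pmax(1L, (lv + 2L * p - k) %/% s + 1L)
}

## ---- convolution ----------------------------------------------------------

# X: C_in x (B*L). W: C_out x (k*C_in), kernel tap j occupying columns
# ((j-1)*C_in+1):(j*C_in).
conv1d_forward <- function(X, B, L, lengths, W, k, stride, need_cache = FALSE) {
  C_in <- nrow(X)
  p <- (k - 1L) %/% 2L
  Lp <- L + 2L * p
  Lout <- (L + 2L * p - k) %/% stride + 1L
  len_out <- nn_out_len(lengths, k, stride)

  Xp <- matrix(0, C_in, B * Lp)
  idx_orig <- as.vector(outer(seq_len(L) + p, (seq_len(B) - 1L) * Lp, "+"))
  Xp[, idx_orig] <- X

  base_out <- stride * (seq_len(Lout) - 1L)
  offs <- (seq_len(B) - 1L) * Lp
  Xcol <- matrix(0, k * C_in, B * Lout)
  cols_j <- vector("list", k)
  for (j in seq_len(k)) {
    cj <- as.vector(outer(base_out + j, offs, "+"))
    cols_j[[j]] <- cj
    Xcol[((j - 1L) * C_in + 1L):(j * C_in), ] <- Xp[, cj, drop = FALSE]
  }
  Y <- W %*% Xcol
  valid <- nn_valid_mask(len_out, Lout)
  vmask <- nn_cmask(valid, nrow(W))
  Y <- Y * vmask
  cache <- NULL
  if (need_cache) {
    # keep the (smaller) padded input; the im2col matrix is regathered in
    # the backward pass, trading a little compute for much less live memory
    cache <- list(Xp = Xp, cols_j = cols_j, idx_orig = idx_orig, vmask = vmask,
                  B = B, Lp = Lp, k = k, C_in = C_in, W = W)
  }
  list(Y = Y, L = Lout, lengths = len_out, valid = valid, vmask = vmask,
       cache = cache)
}

conv1d_backward <- function(cache, dY) {
  dY <- dY * cache$vmask
  k <- cache$k; C_in <- cache$C_in
  Xcol <- matrix(0, k * C_in, ncol(dY))
  for (j in seq_len(k)) {
    Xcol[((j - 1L) * C_in + 1L):(j * C_in), ] <-
      cache$Xp[, cache$cols_j[[j]], drop = FALSE]
  }
  dW <- tcrossprod(dY, Xcol)
  dXcol <- crossprod(cache$W, dY)
  dXp <- matrix(0, C_in, cache$B * cache$Lp)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * C_in + 1L):(j * C_in)
    cj <- cache$cols_j[[j]]
    dXp[, cj] <- dXp[, cj] + dXcol[rows, , drop = FALSE]
  }
  list(dX = dXp[, cache$idx_orig, drop = FALSE], dW = dW)
}

## ---- batch normalization (masked) -----------------------------------------

# Statistics are computed over valid positions only; padded columns are zero
# on entry, so plain row sums divided by the valid count give the masked
# moments without subsetting.
bn_forward <- function(X, valid, vmask, gamma, beta, run_mean, run_var,
                       training, momentum = 0.1, eps = 1e-5) {
  m <- sum(valid)
  if (training) {
    mu <- rowSums(X) / m
    v <- pmax(rowSums(X * X) / m - mu^2, 0)
    new_mean <- (1 - momentum) * run_mean + momentum * mu
    new_var <- (1 - momentum) * run_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- run_mean; v <- run_var
    new_mean <- run_mean; new_var <- run_var
  }
  inv_std <- 1 / sqrt(v + eps)
  xhat <- (inv_std * X + (-mu * inv_std)) * vmask
  Y <- (gamma * xhat + beta) * vmask
  list(Y = Y, run_mean = new_mean, run_var = new_var,
       cache = list(xhat = xhat, inv_std = inv_std, gamma = gamma,
                    vmask = vmask, m = m, training = training))
}

bn_backward <- function(cache, dY) {
  dY <- dY * cache$vmask
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  if (!cache$training) {
    dX <- ((cache$gamma * cache$inv_std) * dY) * cache$vmask
    return(list(dX = dX, dgamma = dgamma, dbeta = dbeta))
  }
  m <- cache$m
  dxhat <- cache$gamma * dY
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dX <- (m * dxhat - s1) - s2 * cache$xhat
  dX <- ((cache$inv_std / m) * dX) * cache$vmask
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations / pooling ------------------------------------------------

relu_forward <- function(X) {
  M <- X > 0
  list(Y = X * M, cache = M)
}

relu_backward <- function(cache, dY) dY * cache

# masked global average pool: C x (B*L) -> B x C over valid steps only
pool_forward <- function(X, B, L, lengths, valid) {
  S <- rowsum(t(X) * valid, group = rep(seq_len(B), each = L), reorder = FALSE)
  list(Y = S / lengths,
       cache = list(B = B, L = L, lengths = lengths, valid = valid, C = nrow(X)))
}

pool_backward <- function(cache, dY) {
  # dY: B x C -> C x (B*L)
  dT <- t(dY / cache$lengths)
  dX <- dT[, rep(seq_len(cache$B), each = cache$L), drop = FALSE]
  dX * nn_cmask(cache$valid, cache$C)
}

## ---- optimizer -------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
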
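# Compact 1-D residual network (ResNet18 topology: a 7-tap stem plus four
# stages of two residual blocks each, channel width doubling and stride-2
# downsampling at each stage boundary) producing a per-waveform embedding
# by masked global average pooling, with a linear risk head trained on the
# Cox partial likelihood. Widths default to 8..64 rather than 64..512:
# the inputs are ~30-120 steps of a single channel, for which the full
# ImageNet width is far past saturation, and the narrow net trains in
# minutes on one CPU; the width is configurable.

#' Extractor configuration
#'
#' @param width0 Channel width of the first stage (doubles per stage, so the
#'   embedding dimension is `8 * width0`).
#' @param blocks Residual blocks per stage (length 4).
#' @param stem_kernel,kernel Kernel sizes (odd) of the stem and block convs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size; risk sets for the partial-likelihood
#'   loss are formed within each minibatch, so it should be large enough to
#'   contain events (>= 256 recommended at a ~3 percent event rate).
#' @param epochs Training epochs.
#' @param sigma Brownian tape-speed augmentation volatility (0 disables).
#' @param seed RNG seed for init, shuffling and augmentation.
#' @return An `extractor_config` list.
#' @export
extractor_config <- function(width0 = 8L, blocks = c(2L, 2L, 2L, 2L),
                             stem_kernel = 7L, kernel = 3L,
                             lr = 2e-3, batch_size = 256L, epochs = 8L,
                             sigma = 0.05, seed = 1L) {
  stopifnot(width0 >= 1, length(blocks) == 4, all(blocks >= 1),
            stem_kernel %% 2 == 1, kernel %% 2 == 1,
            lr > 0, batch_size >= 2, epochs >= 1, sigma >= 0)
  structure(list(width0 = as.integer(width0), blocks = as.integer(blocks),
                 stem_kernel = as.integer(stem_kernel), kernel = as.integer(kernel),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), sigma = sigma, seed = as.integer(seed),
                 embedding_dim = as.integer(width0 * 8L)),
            class = "extractor_config")
}

# He-normal conv weight, C_out x (k*C_in)
.rn_conv_w <- function(k, c_in, c_out) {
  matrix(stats::rnorm(k * c_in * c_out, sd = sqrt(2 / (k * c_in))), c_out, k * c_in)
}

# Parameter and running-stat initialization. The final BN scale of each
# block starts at zero so every residual block begins as the identity.
resnet_init <- function(config) {
  params <- list(); running <- list()
  add_bn <- function(name, c) {
    params[[paste0(name, ".gamma")]] <<- rep(1, c)
    params[[paste0(name, ".beta")]] <<- rep(0, c)
    running[[paste0(name, ".mean")]] <<- rep(0, c)
    running[[paste0(name, ".var")]] <<- rep(1, c)
  }
  w0 <- config$width0
  params[["stem.conv.W"]] <- .rn_conv_w(config$stem_kernel, 1L, w0)
  add_bn("stem.bn", w0)
  c_in <- w0
  for (s in 1:4) {
    c_out <- w0 * 2^(s - 1)
    for (b in seq_len(config$blocks[s])) {
      nm <- sprintf("s%d.b%d", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      params[[paste0(nm, ".conv1.W")]] <- .rn_conv_w(config$kernel, c_in, c_out)
      add_bn(paste0(nm, ".bn1"), c_out)
      params[[paste0(nm, ".conv2.W")]] <- .rn_conv_w(config$kernel, c_out, c_out)
      add_bn(paste0(nm, ".bn2"), c_out)
      params[[paste0(nm, ".bn2.gamma")]] <- rep(0, c_out)
      if (stride > 1L || c_in != c_out) {
        params[[paste0(nm, ".skip.W")]] <- .rn_conv_w(1L, c_in, c_out)
        add_bn(paste0(nm, ".skipbn"), c_out)
      }
      c_in <- c_out
    }
  }
  d <- config$embedding_dim
  params[["head.W"]] <- matrix(stats::rnorm(d, sd = 1 / sqrt(d)), d, 1)
  params[["head.b"]] <- 0
  list(params = params, running = running)
}

# One residual block, forward. Returns Y, new spatial state, cache, and
# updated running stats.
.rn_block_fwd <- function(nm, X, B, L, lengths, params, running, stride,
                          kernel, training, need_cache) {
  cache <- list(nm = nm, stride = stride)
  cv1 <- conv1d_forward(X, B, L, lengths, params[[paste0(nm, ".conv1.W")]],
                        kernel, stride, need_cache)
  bn1 <- bn_forward(cv1$Y, cv1$valid, cv1$vmask, params[[paste0(nm, ".bn1.gamma")]],
                    params[[paste0(nm, ".bn1.beta")]],
                    running[[paste0(nm, ".bn1.mean")]], running[[paste0(nm, ".bn1.var")]],
                    training)
  running[[paste0(nm, ".bn1.mean")]] <- bn1$run_mean
  running[[paste0(nm, ".bn1.var")]] <- bn1$run_var
  r1 <- relu_forward(bn1$Y)
  cv2 <- conv1d_forward(r1$Y, B, cv1$L, cv1$lengths, params[[paste0(nm, ".conv2.W")]],
                        kernel, 1L, need_cache)
  bn2 <- bn_forward(cv2$Y, cv2$valid, cv2$vmask, params[[paste0(nm, ".bn2.gamma")]],
                    params[[paste0(nm, ".bn2.beta")]],
                    running[[paste0(nm, ".bn2.mean")]], running[[paste0(nm, ".bn2.var")]],
                    training)
  running[[paste0(nm, ".bn2.mean")]] <- bn2$run_mean
  running[[paste0(nm, ".bn2.var")]] <- bn2$run_var

  has_skip <- !is.null(params[[paste0(nm, ".skip.W")]])
  if (has_skip) {
    sk <- conv1d_forward(X, B, L, lengths, params[[paste0(nm, ".skip.W")]],
                         1L, stride, need_cache)
    skbn <- bn_forward(sk$Y, sk$valid, sk$vmask, params[[paste0(nm, ".skipbn.gamma")]],
                       params[[paste0(nm, ".skipbn.beta")]],
                       running[[paste0(nm, ".skipbn.mean")]],
                       running[[paste0(nm, ".skipbn.var")]], training)
    running[[paste0(nm, ".skipbn.mean")]] <- skbn$run_mean
    running[[paste0(nm, ".skipbn.var")]] <- skbn$run_var
    identity <- skbn$Y
  } else identity <- X
  r2 <- relu_forward(bn2$Y + identity)
  Y <- r2$Y * cv2$vmask
  if (need_cache) {
    cache$cv1 <- cv1$cache; cache$bn1 <- bn1$cache; cache$r1 <- r1$cache
    cache$cv2 <- cv2$cache; cache$bn2 <- bn2$cache; cache$r2 <- r2$cache
    cache$has_skip <- has_skip
    if (has_skip) { cache$sk <- sk$cache; cache$skbn <- skbn$cache }
  }
  list(Y = Y, L = cv2$L, lengths = cv2$lengths, valid = cv2$valid,
       cache = cache, running = running)
}

.rn_block_bwd <- function(cache, dY, grads, kernel) {
  nm <- cache$nm
  dY <- dY * cache$bn2$vmask
  d_r2 <- relu_backward(cache$r2, dY)
  b2 <- bn_backward(cache$bn2, d_r2)
  grads[[paste0(nm, ".bn2.gamma")]] <- b2$dgamma
  grads[[paste0(nm, ".bn2.beta")]] <- b2$dbeta
  c2 <- conv1d_backward(cache$cv2, b2$dX)
  grads[[paste0(nm, ".conv2.W")]] <- c2$dW
  d_r1 <- relu_backward(cache$r1, c2$dX)
  b1 <- bn_backward(cache$bn1, d_r1)
  grads[[paste0(nm, ".bn1.gamma")]] <- b1$dgamma
  grads[[paste0(nm, ".bn1.beta")]] <- b1$dbeta
  c1 <- conv1d_backward(cache$cv1, b1$dX)
  grads[[paste0(nm, ".conv1.W")]] <- c1$dW
  dX <- c1$dX
  if (cache$has_skip) {
    sb <- bn_backward(cache$skbn, d_r2)
    grads[[paste0(nm, ".skipbn.gamma")]] <- sb$dgamma
    grads[[paste0(nm, ".skipbn.beta")]] <- sb$dbeta
    sc <- conv1d_backward(cache$sk, sb$dX)
    grads[[paste0(nm, ".skip.W")]] <- sc$dW
    dX <- dX + sc$dX
  } else dX <- dX + d_r2
  list(dX = dX, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full network forward. batch: padded_batch. Returns embeddings (B x D),
# risk scores (length B), caches for backward, and updated running stats.
resnet_forward <- function(params, running, config, batch,
                           training = FALSE, need_cache = FALSE) {
  B <- nrow(batch$values); L <- ncol(batch$values)
  lengths <- batch$lengths
  X <- matrix(as.vector(t(batch$values)), nrow = 1)   # column n = (b-1)*L + t
  caches <- list()

  cv <- conv1d_forward(X, B, L, lengths, params[["stem.conv.W"]],
                       config$stem_kernel, 1L, need_cache)
  bn <- bn_forward(cv$Y, cv$valid, cv$vmask, params[["stem.bn.gamma"]],
                   params[["stem.bn.beta"]],
                   running[["stem.bn.mean"]], running[["stem.bn.var"]], training)
  running[["stem.bn.mean"]] <- bn$run_mean
  running[["stem.bn.var"]] <- bn$run_var
  rl <- relu_forward(bn$Y)
  caches$stem <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache)
  Y <- rl$Y; Lc <- cv$L; lens <- cv$lengths

  for (s in 1:4) {
    for (b in seq_len(config$blocks[s])) {
      nm <- sprintf("s%d.b%d", s, b)
      stride <- if (s > 1 && b == 1) 2L else 1L
      blk <- .rn_block_fwd(nm, Y, B, Lc, lens, params, running, stride,
                           config$kernel, training, need_cache)
      running <- blk$running
      caches[[nm]] <- blk$cache
      Y <- blk$Y; Lc <- blk$L; lens <- blk$lengths
    }
  }
  valid <- nn_valid_mask(lens, Lc)
  pl <- pool_forward(Y, B, Lc, lens, valid)
  emb <- pl$Y
  risk <- as.vector(emb %*% params[["head.W"]]) + params[["head.b"]]
  caches$pool <- pl$cache
  caches$emb <- emb
  list(emb = emb, risk = risk, running = running,
       caches = if (need_cache) caches else NULL, config = config)
}

# Backward pass. d_risk: length-B vector (may be NULL); d_emb: B x D matrix
# of upstream embedding gradients (may be NULL). Returns parameter grads
# and, if need_dx, the gradient w.r.t. the input waveform matrix (B x L).
resnet_backward <- function(params, config, caches, d_risk = NULL, d_emb = NULL,
                            need_dx = FALSE) {
  emb <- caches$emb
  B <- nrow(emb)
  grads <- list()
  dE <- matrix(0, B, ncol(emb))
  if (!is.null(d_emb)) dE <- dE + d_emb
  if (!is.null(d_risk)) {
    grads[["head.W"]] <- crossprod(emb, d_risk)
    grads[["head.b"]] <- sum(d_risk)
    dE <- dE + tcrossprod(d_risk, params[["head.W"]])
  } else {
    grads[["head.W"]] <- matrix(0, ncol(emb), 1)
    grads[["head.b"]] <- 0
  }
  dY <- pool_backward(caches$pool, dE)

  for (s in 4:1) {
    for (b in rev(seq_len(config$blocks[s]))) {
      nm <- sprintf("s%d.b%d", s, b)
      res <- .rn_block_bwd(caches[[nm]], dY, grads, config$kernel)
      dY <- res$dX; grads <- res$grads
    }
  }
  d_rl <- relu_backward(caches$stem$rl, dY)
  bs <- bn_backward(caches$stem$bn, d_rl)
  grads[["stem.bn.gamma"]] <- bs$dgamma
  grads[["stem.bn.beta"]] <- bs$dbeta
  cs <- conv1d_backward(caches$stem$cv, bs$dX)
  grads[["stem.conv.W"]] <- cs$dW
  out <- list(grads = grads)
  if (need_dx) {
    L <- length(cs$dX) / B
    out$dX <- matrix(as.vector(cs$dX), nrow = B, ncol = L, byrow = TRUE)
  }
  out
}
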
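test_that("Cox partial-likelihood loss matches closed forms", {
  # four subjects, equal scores, single event at the earliest time: log 4
  expect_equal(cox_partial_nll(rep(0, 4), c(1, 2, 3, 4), c(1, 0, 0, 0)), log(4))
  # two subjects, scores (1, 0), event first: log(1 + e^-1)
  expect_equal(cox_partial_nll(c(1, 0), c(1, 2), c(1, 0)), log(1 + exp(-1)))
})

test_that("loss is invariant to score shifts and subject reordering", {
  set.seed(3)
  for (r in 1:20) {
    n <- 30
    s <- rnorm(n); t <- sample(1:10, n, replace = TRUE); e <- rbinom(n, 1, 0.5)
    if (sum(e) == 0) e[1] <- 1
    l0 <- cox_partial_nll(s, t, e)
    expect_equal(cox_partial_nll(s + 7.3, t, e), l0, tolerance = 1e-10)
    p <- sample(n)
    expect_equal(cox_partial_nll(s[p], t[p], e[p]), l0, tolerance = 1e-12)
  }
  expect_error(cox_partial_nll(rnorm(5), 1:5, rep(0, 5)), "zero events")
})

test_that("loss gradient matches finite differences", {
  set.seed(8)
  n <- 12
  s <- rnorm(n); t <- sample(1:6, n, replace = TRUE); e <- c(1, rbinom(n - 1, 1, 0.5))
  g <- cox_partial_nll(s, t, e, gradient = TRUE)
  fd <- vapply(seq_len(n), function(i) {
    h <- 1e-6; sp <- s; sp[i] <- sp[i] + h
    (cox_partial_nll(sp, t, e) - cox_partial_nll(s, t, e)) / h
  }, numeric(1))
  expect_lt(max(abs(g$grad - fd)), 1e-5)
})

test_that("the extractor is deterministic, shape-correct and padding-invariant", {
  cfg <- extractor_config(width0 = 4L, seed = 5L)
  mod <- init_extractor(cfg)
  f <- build_extractor(mod)
  set.seed(9)
  x <- runif(47)
  # identical waves give identical embedding rows
  b <- structure(list(values = rbind(c(x, rep(0, 3)), c(x, rep(0, 3))),
                      lengths = c(47L, 47L), ids = 1:2), class = "padded_batch")
  out <- f(b)
  expect_equal(dim(out$emb), c(2L, cfg$embedding_dim))
  expect_identical(out$emb[1, ], out$emb[2, ])
  # padding to a longer batch length changes nothing
  b2 <- structure(list(values = rbind(c(x, rep(0, 13))), lengths = 47L, ids = 1),
                  class = "padded_batch")
  expect_lt(max(abs(f(b2)$emb[1, ] - out$emb[1, ])), 1e-6)
  # rerunning with the same weights is bitwise identical
  expect_identical(f(b)$emb, out$emb)
})

test_that("network gradients agree with finite differences", {
  set.seed(7)
  cfg <- extractor_config(width0 = 2L, seed = 3L)
  mod <- init_extractor(cfg)
  # nonzero block-output scales so no path is degenerately zero
  for (nm in names(mod$params)) {
    if (grepl("gamma", nm)) mod$params[[nm]] <- runif(length(mod$params[[nm]]), 0.5, 1.5)
  }
  B <- 4L; L <- 36L
  lens <- c(36L, 30L, 25L, 33L)
  vals <- matrix(0, B, L)
  for (i in seq_len(B)) vals[i, seq_len(lens[i])] <- runif(lens[i])
  batch <- list(values = vals, lengths = lens)
  t <- c(3, 1, 4, 2); e <- c(1, 1, 0, 1)
  loss_of <- function(params) {
    cox_partial_nll(ppgsurv:::resnet_forward(params, mod$running, cfg, batch,
                                             training = TRUE)$risk, t, e)
  }
  fwd <- ppgsurv:::resnet_forward(mod$params, mod$running, cfg, batch,
                                  training = TRUE, need_cache = TRUE)
  lg <- cox_partial_nll(fwd$risk, t, e, gradient = TRUE)
  bwd <- ppgsurv:::resnet_backward(mod$params, cfg, fwd$caches, d_risk = lg$grad)
  for (nm in c("stem.conv.W", "s2.b1.conv1.W", "s2.b1.skip.W", "s4.b2.conv2.W",
               "s3.b1.bn1.gamma", "s1.b2.bn2.beta", "head.W", "head.b")) {
    p <- mod$params[[nm]]
    for (i in sample(length(p), min(2, length(p)))) {
      h <- 1e-5
      pp <- mod$params; pp[[nm]][i] <- pp[[nm]][i] + h
      f1 <- loss_of(pp)
      pp[[nm]][i] <- pp[[nm]][i] - 2 * h
      f0 <- loss_of(pp)
      fd <- (f1 - f0) / (2 * h)
      an <- bwd$grads[[nm]][i]
      expect_lt(min(abs(fd - an), abs(fd - an) / (abs(fd) + abs(an) + 1e-8)), 1e-4)
    }
  }
})

test_that("training selects the tune-optimal checkpoint and is seed-reproducible", {
  set.seed(31)
  # tiny synthetic problem with a blunt amplitude-driven hazard
  n <- 300
  amp <- runif(n, 0.3, 1)
  u <- (0:99) / 99
  waves <- lapply(seq_len(n), function(i) {
    raw_pulse_wave(amp[i] * exp(-(u - 0.3)^2 / 0.01) +
                     0.4 * exp(-(u - 0.6)^2 / 0.02) + rnorm(100, 0, 0.01), 60)
  })
  batch <- preprocess_waves(waves)
  t <- rexp(n) / exp(1.5 * scale(amp)[, 1])
  e <- as.integer(t < quantile(t, 0.5)); tt <- pmin(t, quantile(t, 0.5))
  idx_tr <- 1:200; idx_tu <- 201:300
  sub <- function(i) structure(list(values = batch$values[i, , drop = FALSE],
                                    lengths = batch$lengths[i], ids = i),
                               class = "padded_batch")
  cfg <- extractor_config(width0 = 2L, epochs = 2L, batch_size = 100L,
                          lr = 1e-3, seed = 11L)
  m1 <- train_extractor(sub(idx_tr), tt[idx_tr], e[idx_tr],
                        sub(idx_tu), tt[idx_tu], e[idx_tu], cfg)
  m2 <- train_extractor(sub(idx_tr), tt[idx_tr], e[idx_tr],
                        sub(idx_tu), tt[idx_tu], e[idx_tu], cfg)
  expect_identical(m1$params, m2$params)
  expect_equal(m1$best_epoch, which.min(m1$log$tune_loss))
  expect_lte(min(m1$log$tune_loss), m1$log$tune_loss[1])
  expect_error(train_extractor(sub(idx_tr), tt[idx_tr], rep(0, 200),
                               sub(idx_tu), tt[idx_tu], e[idx_tu], cfg),
               "events")
})

test_that("PCA projection is orthonormal, train-centred and matches an eigen oracle", {
  set.seed(12)
  X <- matrix(rnorm(50 * 8), 50, 8) %*% diag(c(4, 3, 2, 1.5, 1, .5, .3, .1))
  proj <- fit_pca(X, k = 5)
  expect_equal(crossprod(proj$loadings), diag(5), tolerance = 1e-8)
  expect_true(all(diff(proj$explained) <= 1e-12))
  sc <- project_pca(X, proj)
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  expect_equal(colnames(sc), paste0("ppg", 1:5))

  # reconstruction error equals the brute-force eigendecomposition answer
  Xc <- scale(X, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(Xc) / nrow(Xc), symmetric = TRUE)
  V <- eig$vectors[, 1:5]
  recon_oracle <- sum((Xc - Xc %*% V %*% t(V))^2)
  recon <- sum((Xc - sc %*% t(proj$loadings))^2)
  expect_equal(recon, recon_oracle, tolerance = 1e-8)
})
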
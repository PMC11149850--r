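# First modelling stage: train the 1-D residual network with a Cox
# partial-likelihood loss on minibatch risk sets, select the epoch with the
# best tune-split pseudolikelihood, compute embeddings, and reduce them by
# PCA to the five deep PPG features.

#' Negative Cox partial log-likelihood of raw risk scores
#'
#' Breslow handling of tied event times: every event at a tied time uses
#' the full risk set including its ties. The value is the mean over events
#' of \eqn{-(r_i - \log \sum_{j \in R(t_i)} e^{r_j})}; it is invariant to
#' adding a constant to all scores and to reordering subjects.
#'
#' @param scores Real risk scores, one per subject.
#' @param times Follow-up times.
#' @param events Event indicators (0/1).
#' @param gradient If `TRUE`, also return the gradient w.r.t. `scores`.
#' @return The scalar loss, or (with `gradient`) a list `value`/`grad`.
#' @export
cox_partial_nll <- function(scores, times, events, gradient = FALSE) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n, n >= 2)
  events <- as.numeric(events)
  D <- sum(events)
  if (D < 1) stop("cox_partial_nll undefined with zero events")
  ord <- order(times)
  r <- scores[ord]; t_s <- times[ord]; e_s <- events[ord]
  rc <- r - max(r)
  er <- exp(rc)
  # risk-set sums: S_i = sum_{t_j >= t_i} exp(r_j), shared within tied groups
  rev_cs <- rev(cumsum(rev(er)))
  first_of_group <- !duplicated(t_s)
  S <- rev_cs[ave(seq_len(n), cumsum(first_of_group), FUN = function(i) i[1])]
  value <- -(sum(e_s * (rc - log(S)))) / D
  if (!gradient) return(value)
  # grad_j = (1/D) * (exp(r_j) * sum_{event groups g: t_g <= t_j} d_g/S_g - e_j)
  grp <- cumsum(first_of_group)
  d_g <- rowsum(e_s, grp, reorder = FALSE)[, 1]
  S_g <- S[first_of_group]
  A <- cumsum(d_g / S_g)          # per group, ascending time
  G <- A[grp]
  grad_s <- (er * G - e_s) / D
  grad <- numeric(n); grad[ord] <- grad_s
  list(value = value, grad = grad)
}

#' Build an extractor function from weights
#'
#' @param model A trained extractor (list with `params`, `running`,
#'   `config`), e.g. from [train_extractor()] or [init_extractor()].
#' @return `function(batch)` mapping a `padded_batch` to a list with
#'   `emb` (n x embedding_dim) and `risk` (length n); evaluation mode, so
#'   deterministic and padding-invariant.
#' @export
build_extractor <- function(model) {
  force(model)
  function(batch) {
    out <- resnet_forward(model$params, model$running, model$config, batch,
                          training = FALSE, need_cache = FALSE)
    list(emb = out$emb, risk = out$risk)
  }
}

#' Initialize an untrained extractor
#'
#' @param config An [extractor_config()].
#' @return An extractor model list (`params`, `running`, `config`).
#' @export
init_extractor <- function(config = extractor_config()) {
  set.seed(config$seed)
  st <- resnet_init(config)
  list(params = st$params, running = st$running, config = config, log = NULL)
}

#' Train the PPG feature extractor
#'
#' Minimizes the minibatch Cox partial-likelihood loss with Adam on the
#' train split (with Brownian tape-speed augmentation) and returns the
#' weights with the best tune-split pseudolikelihood over epochs.
#'
#' @param train_batch,tune_batch `padded_batch` objects (normalized waves).
#' @param train_times,train_events,tune_times,tune_events Survival outcomes
#'   aligned to the batch rows.
#' @param config An [extractor_config()].
#' @param verbose Print per-epoch losses.
#' @return Extractor model: `params`, `running`, `config`, `log`
#'   (per-epoch train/tune loss), `best_epoch`.
#' @export
train_extractor <- function(train_batch, train_times, train_events,
                            tune_batch, tune_times, tune_events,
                            config = extractor_config(), verbose = FALSE) {
  if (sum(train_events) < 1 || sum(tune_events) < 1) {
    stop("both train and tune splits must contain events")
  }
  set.seed(config$seed)
  st <- resnet_init(config)
  params <- st$params; running <- st$running
  opt <- adam_init(params)
  n <- nrow(train_batch$values)
  bs <- config$batch_size
  log <- data.frame(epoch = integer(0), train_loss = numeric(0), tune_loss = numeric(0))
  best <- list(loss = Inf, params = params, running = running, epoch = 0L)

  for (epoch in seq_len(config$epochs)) {
    idx <- sample.int(n)
    starts <- seq(1L, n, by = bs)
    ep_loss <- 0; ep_events <- 0
    for (s0 in starts) {
      ib <- idx[s0:min(s0 + bs - 1L, n)]
      if (length(ib) < 16L || sum(train_events[ib]) < 1) next
      vals <- train_batch$values[ib, , drop = FALSE]
      if (config$sigma > 0) {
        vals <- augment_batch(vals, train_batch$lengths[ib], config$sigma, stats::rnorm)
      }
      mb <- list(values = vals, lengths = train_batch$lengths[ib])
      fwd <- resnet_forward(params, running, config, mb,
                            training = TRUE, need_cache = TRUE)
      running <- fwd$running
      loss <- cox_partial_nll(fwd$risk, train_times[ib], train_events[ib],
                              gradient = TRUE)
      if (!is.finite(loss$value)) stop("training diverged (non-finite loss) at epoch ", epoch)
      bwd <- resnet_backward(params, config, fwd$caches, d_risk = loss$grad)
      upd <- adam_step(params, bwd$grads, opt, lr = config$lr)
      params <- upd$params; opt <- upd$state
      ep_loss <- ep_loss + loss$value * sum(train_events[ib])
      ep_events <- ep_events + sum(train_events[ib])
    }
    tune_risk <- .extract_risk(params, running, config, tune_batch)
    tune_loss <- cox_partial_nll(tune_risk, tune_times, tune_events)
    log <- rbind(log, data.frame(epoch = epoch, train_loss = ep_loss / max(ep_events, 1),
                                 tune_loss = tune_loss))
    if (verbose) message(sprintf("epoch %d train %.4f tune %.4f", epoch,
                                 ep_loss / max(ep_events, 1), tune_loss))
    if (tune_loss < best$loss) {
      best <- list(loss = tune_loss, params = params, running = running, epoch = epoch)
    }
  }
  list(params = best$params, running = best$running, config = config,
       log = log, best_epoch = best$epoch)
}

# chunked eval-mode risk scores
.extract_risk <- function(params, running, config, batch, chunk = 512L) {
  n <- nrow(batch$values)
  out <- numeric(n)
  for (s0 in seq(1L, n, by = chunk)) {
    ii <- s0:min(s0 + chunk - 1L, n)
    mb <- list(values = batch$values[ii, , drop = FALSE], lengths = batch$lengths[ii])
    out[ii] <- resnet_forward(params, running, config, mb)$risk
  }
  out
}

#' Compute embeddings for a batch of waveforms
#'
#' Evaluation mode (no augmentation, frozen normalization statistics), so
#' results are deterministic, order-preserving and padding-invariant.
#'
#' @param model Trained extractor.
#' @param batch A `padded_batch`.
#' @param chunk Rows per forward chunk.
#' @return List: `emb` (n x embedding_dim, rownames = batch ids), `risk`.
#' @export
compute_embeddings <- function(model, batch, chunk = 512L) {
  n <- nrow(batch$values)
  emb <- matrix(0, n, model$config$embedding_dim)
  risk <- numeric(n)
  for (s0 in seq(1L, n, by = chunk)) {
    ii <- s0:min(s0 + chunk - 1L, n)
    mb <- list(values = batch$values[ii, , drop = FALSE], lengths = batch$lengths[ii])
    out <- resnet_forward(model$params, model$running, model$config, mb)
    emb[ii, ] <- out$emb; risk[ii] <- out$risk
  }
  rownames(emb) <- as.character(batch$ids)
  list(emb = emb, risk = risk)
}

#' Fit a PCA projection on train-split embeddings
#'
#' @param emb Embedding matrix (train split only).
#' @param k Number of components (default 5).
#' @return `pca_projection`: `mean`, `loadings` (orthonormal columns),
#'   `explained` (variance fractions, non-increasing).
#' @export
fit_pca <- function(emb, k = 5L) {
  stopifnot(nrow(emb) > ncol(emb))
  mu <- colMeans(emb)
  Xc <- sweep(emb, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(k, ncol(emb)))
  k_eff <- min(k, sum(sv$d > 1e-10))
  structure(list(mean = mu, loadings = sv$v[, seq_len(k_eff), drop = FALSE],
                 explained = (sv$d^2 / sum(sv$d^2))[seq_len(k_eff)], k = k_eff),
            class = "pca_projection")
}

#' Project embeddings onto fitted principal components
#'
#' @param emb Embedding matrix.
#' @param proj A [fit_pca()] projection.
#' @param prefix Column-name prefix for the scores.
#' @return n x k score matrix with columns `ppg1..ppgk`.
#' @export
project_pca <- function(emb, proj, prefix = "ppg") {
  sc <- sweep(emb, 2, proj$mean) %*% proj$loadings
  colnames(sc) <- paste0(prefix, seq_len(ncol(sc)))
  rownames(sc) <- rownames(emb)
  sc
}
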
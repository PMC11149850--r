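# Interpretability: integrated-gradients attribution of the Cox linear
# predictor with respect to the input waveform, quantile-averaged
# waveforms, Spearman correlation tables between deep and engineered PPG
# features, and coefficient / hazard-ratio reports.

#' Integrated gradients along the straight path from an all-zeros baseline
#'
#' \eqn{IG_i = x_i \cdot \frac{1}{m}\sum_{k=1}^m \partial F/\partial x_i
#' \big((k/m) x\big)}. The completeness residual
#' \eqn{\sum_i IG_i - (F(x) - F(0))} is reported, never hidden.
#'
#' @param f `function(X)` taking a matrix of inputs (rows = scaled copies
#'   of the waveform) and returning `list(values, grads)` with per-row
#'   scores and input gradients. See [dls_waveform_scorer()].
#' @param x The input waveform (numeric vector, valid part only).
#' @param m Number of path steps.
#' @return `saliency_map`: `attributions` (length of `x`), `residual`,
#'   `score`, `baseline_score`, `m`.
#' @export
integrated_gradients <- function(f, x, m = 64L) {
  x <- as.numeric(x)
  alphas <- seq_len(m) / m
  Xpath <- outer(alphas, x)
  out <- f(Xpath)
  if (!all(is.finite(out$grads))) stop("non-finite gradients along the path")
  avg_grad <- colMeans(out$grads)
  ig <- x * avg_grad
  ends <- f(rbind(x, 0 * x))
  residual <- sum(ig) - (ends$values[1] - ends$values[2])
  structure(list(attributions = ig, residual = residual,
                 score = ends$values[1], baseline_score = ends$values[2], m = m),
            class = "saliency_map")
}

#' Waveform scorer for the deep survival pipeline
#'
#' Builds the differentiable map from a (normalized, uniform-grid)
#' waveform to the Cox log partial hazard contribution of the deep PPG
#' features, holding metadata fixed: network embedding -> PCA scores ->
#' standardized features -> Cox coefficients (including any age
#' interactions, evaluated at `age_z`). Gradients flow back through the
#' network in evaluation mode.
#'
#' @param extractor Trained extractor model.
#' @param proj PCA projection from [fit_pca()].
#' @param cox A fitted `ppg_cox_model` containing `ppg1..ppg5` terms.
#' @param age_z Standardized age at which interaction terms are evaluated
#'   (0 = train-split mean age).
#' @return `function(X)` suitable for [integrated_gradients()].
#' @export
dls_waveform_scorer <- function(extractor, proj, cox, age_z = 0) {
  ppg_names <- paste0("ppg", seq_len(ncol(proj$loadings)))
  beta_eff <- vapply(ppg_names, function(nm) {
    b <- unname(cox$beta[nm])
    if (is.na(b)) b <- 0
    bi <- unname(cox$beta[paste0("age:", nm)])
    if (!is.na(bi)) b <- b + age_z * bi
    b
  }, numeric(1))
  sds <- vapply(ppg_names, function(nm) cox$spec$scaler[[nm]]$sd, numeric(1))
  # d lp / d emb: loadings %*% (beta / sd); constant offsets (means) do not
  # affect gradients and cancel in F(x) - F(0)
  v <- as.vector(proj$loadings %*% (beta_eff / sds))
  function(X) {
    X <- rbind(X)
    B <- nrow(X); L <- ncol(X)
    mb <- list(values = X, lengths = rep(L, B))
    fwd <- resnet_forward(extractor$params, extractor$running, extractor$config,
                          mb, training = FALSE, need_cache = TRUE)
    values <- as.vector(fwd$emb %*% v)
    d_emb <- matrix(v, B, length(v), byrow = TRUE)
    bwd <- resnet_backward(extractor$params, extractor$config, fwd$caches,
                           d_emb = d_emb, need_dx = TRUE)
    list(values = values, grads = bwd$dX)
  }
}

#' Quantile-averaged waveforms
#'
#' For each requested quantile of `values`, selects the `k` subjects whose
#' value lies nearest the quantile (ties broken toward the lower id) and
#' returns the pointwise mean of their display-space waveforms.
#'
#' @param values Per-subject scalar (feature value or predicted risk).
#' @param waves Matrix, one row per subject (common display grid, e.g. the
#'   raw 100-sample space).
#' @param q Quantiles.
#' @param k Subjects averaged per quantile.
#' @return Matrix with one row per quantile (rownames = quantile).
#' @export
quantile_average_waves <- function(values, waves, q = c(0.10, 0.50, 0.90), k = 100L) {
  n <- length(values)
  if (nrow(waves) != n) stop("values and waves misaligned")
  if (n < k) stop("need at least k subjects")
  out <- matrix(0, length(q), ncol(waves))
  rownames(out) <- paste0("q", format(q))
  for (i in seq_along(q)) {
    target <- stats::quantile(values, q[i], type = 7)
    ord <- order(abs(values - target), seq_len(n))   # ties -> lower id
    sel <- ord[seq_len(k)]
    out[i, ] <- colMeans(waves[sel, , drop = FALSE])
  }
  out
}

#' Spearman correlation table between deep and engineered PPG features
#'
#' Rank correlation with average ranks for ties, pairwise complete cases.
#'
#' @param dls_features Data frame/matrix of deep features (ppg1..ppg5).
#' @param morph_features Data frame of engineered morphology features.
#' @return Correlation matrix (deep features x morphology features).
#' @export
feature_correlation_table <- function(dls_features, morph_features) {
  d <- as.matrix(dls_features); m_ <- sapply(morph_features, as.numeric)
  if (nrow(d) < 3) stop("need at least 3 paired observations")
  stats::cor(d, m_, method = "spearman", use = "pairwise.complete.obs")
}

#' Coefficient and hazard-ratio report
#'
#' Univariable Cox coefficient per deep feature plus the multivariable
#' coefficients of a fitted model; hazard ratios are evaluated at a stated
#' age when age interactions are present (\eqn{HR = \exp(\beta +
#' age_z\,\beta_{age:feature})}), reducing to \eqn{\exp(\beta)} without
#' interactions.
#'
#' @param model Fitted `ppg_cox_model`.
#' @param train_df Train-split cohort table (for the univariable fits).
#' @param features Features to report (default the model's).
#' @param at_age Age (years) at which to evaluate interaction HRs; default
#'   the median event age in `train_df`.
#' @return Data frame: feature, univariable/multivariable coefficient,
#'   hazard ratio at `at_age`.
#' @export
coefficient_report <- function(model, train_df, features = NULL, at_age = NULL) {
  if (model$type != "cox") stop("coefficient_report needs a fitted Cox model")
  if (is.null(features)) features <- model$spec$features
  if (is.null(at_age)) at_age <- stats::median(train_df$age[train_df$event == 1])
  age_sc <- model$spec$scaler[["age"]]
  age_z <- if (is.null(age_sc)) 0 else (at_age - age_sc$mean) / age_sc$sd
  rows <- lapply(features, function(f) {
    x <- as.numeric(train_df[[f]])
    ok <- !is.na(x)
    z <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
    uni <- fit_cox_ridge(matrix(z, ncol = 1), train_df$time[ok],
                         train_df$event[ok], lambda = 0)$beta
    b <- unname(model$beta[f]); if (is.na(b)) b <- 0
    bi <- unname(model$beta[paste0("age:", f)])
    eff <- if (is.na(bi)) b else b + age_z * bi
    data.frame(feature = f, coef_univariable = unname(uni),
               coef_multivariable = b,
               coef_age_interaction = if (is.na(bi)) NA_real_ else bi,
               hazard_ratio = exp(eff), at_age = at_age)
  })
  do.call(rbind, rows)
}
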
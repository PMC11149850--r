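# Second modelling stage: ridge-penalized Cox proportional-hazards models
# over named feature sets, a Breslow baseline cumulative hazard for
# absolute ten-year risk, Kaplan-Meier curves and the log-rank test.

DAYS_PER_YEAR <- 365.25
TEN_YEARS_DAYS <- 10 * DAYS_PER_YEAR

# Breslow partial log-likelihood, gradient and (negative) Hessian for a
# given coefficient vector. X already standardized/expanded.
.cox_ll <- function(beta, X, times, events) {
  n <- nrow(X); p <- ncol(X)
  ord <- order(times)
  Xs <- X[ord, , drop = FALSE]; t_s <- times[ord]; e_s <- as.numeric(events[ord])
  lp <- as.vector(Xs %*% beta)
  lpc <- lp - max(lp)
  w <- exp(lpc)
  first <- !duplicated(t_s)
  grp <- cumsum(first)
  G <- max(grp)
  # risk-set cumulants from the largest time down
  revc <- function(v) rev(cumsum(rev(v)))
  S0 <- revc(w)[first]                       # per group
  wX <- Xs * w
  S1 <- apply(wX, 2, function(col) revc(col)[first])   # G x p
  S1 <- matrix(S1, nrow = G)
  d_g <- rowsum(e_s, grp, reorder = FALSE)[, 1]
  ev_groups <- d_g > 0
  ll <- sum(e_s * lpc) - sum(d_g[ev_groups] * log(S0[ev_groups]))
  # gradient: sum_events x_i - sum_g d_g * S1_g/S0_g
  xbar <- S1 / S0
  grad <- colSums(Xs[e_s > 0, , drop = FALSE]) -
    colSums(xbar[ev_groups, , drop = FALSE] * d_g[ev_groups])
  # Hessian: sum_g d_g * (S2_g/S0_g - xbar xbar^T), S2 = sum w x x^T
  H <- matrix(0, p, p)
  # accumulate upper triangle of S2 via cumulative sums
  for (a in seq_len(p)) {
    cols <- a:p
    S2a <- apply(wX[, cols, drop = FALSE] * Xs[, a], 2, function(col) revc(col)[first])
    S2a <- matrix(S2a, nrow = G)
    for (jj in seq_along(cols)) {
      bcol <- cols[jj]
      hab <- sum(d_g[ev_groups] *
                   (S2a[ev_groups, jj] / S0[ev_groups] -
                      xbar[ev_groups, a] * xbar[ev_groups, bcol]))
      H[a, bcol] <- hab; H[bcol, a] <- hab
    }
  }
  list(ll = ll, grad = grad, H = H)
}

#' Fit a ridge-penalized Cox proportional-hazards model
#'
#' Maximizes the Breslow partial log-likelihood minus
#' \eqn{(\lambda/2)\,\lVert\beta\rVert^2} by Newton-Raphson with step
#' halving; convergence when the largest penalized score-gradient component
#' is below `tol`.
#'
#' @param X Numeric design matrix (standardize before calling; see
#'   [fit_feature_set()] for the full workflow).
#' @param times,events Survival outcome.
#' @param lambda Ridge penalty (>= 0).
#' @param tol Gradient convergence tolerance.
#' @param max_iter Newton iteration cap.
#' @return A `cox_ridge_fit`: `beta`, `lambda`, `loglik` (unpenalized, at
#'   `beta`), `iterations`, `converged`.
#' @export
fit_cox_ridge <- function(X, times, events, lambda = 0, tol = 1e-7, max_iter = 50L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("need more subjects than model terms")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in design matrix")
  if (sum(events) < 1) stop("no events")
  if (sum(events) < 10) warning("fewer than 10 events; fit will be unstable")
  beta <- rep(0, p)
  pll <- function(ll, b) ll - lambda / 2 * sum(b^2)
  cur <- .cox_ll(beta, X, times, events)
  for (it in seq_len(max_iter)) {
    g <- cur$grad - lambda * beta
    if (max(abs(g)) < tol) {
      return(structure(list(beta = beta, lambda = lambda, loglik = cur$ll,
                            iterations = it - 1L, converged = TRUE),
                       class = "cox_ridge_fit"))
    }
    Hp <- cur$H + diag(lambda, p)
    step <- solve(Hp, g)
    # step halving on the penalized objective
    f0 <- pll(cur$ll, beta)
    ok <- FALSE
    for (h in 0:30) {
      beta_new <- beta + step / 2^h
      cand <- .cox_ll(beta_new, X, times, events)
      if (is.finite(cand$ll) && pll(cand$ll, beta_new) >= f0 - 1e-12) {
        beta <- beta_new; cur <- cand; ok <- TRUE; break
      }
    }
    if (!ok) stop("Cox ridge fit failed to improve the objective (iteration ", it, ")")
  }
  g <- cur$grad - lambda * beta
  if (max(abs(g)) >= tol) {
    stop("Cox ridge fit did not converge in ", max_iter,
         " iterations (max gradient ", format(max(abs(g))), ")")
  }
  structure(list(beta = beta, lambda = lambda, loglik = cur$ll,
                 iterations = max_iter, converged = TRUE),
            class = "cox_ridge_fit")
}

# unpenalized Breslow partial log-likelihood of fixed coefficients on new data
cox_loglik <- function(beta, X, times, events) {
  .cox_ll(beta, as.matrix(X), times, events)$ll
}

#' Select the ridge penalty on the tune split
#'
#' Fits on the train split at each grid value and returns the penalty whose
#' coefficients maximize the unpenalized tune-split partial likelihood;
#' ties break toward the larger penalty.
#'
#' @param X_train,times_train,events_train Train split.
#' @param X_tune,times_tune,events_tune Tune split.
#' @param grid Candidate penalties.
#' @return List: `lambda`, `tune_loglik` (per grid value), `grid`.
#' @export
tune_ridge <- function(X_train, times_train, events_train,
                       X_tune, times_tune, events_tune,
                       grid = c(0.01, 0.1, 1, 10, 100)) {
  if (!length(grid)) stop("empty penalty grid")
  lls <- rep(NA_real_, length(grid))
  for (i in seq_along(grid)) {
    fit <- tryCatch(fit_cox_ridge(X_train, times_train, events_train, grid[i]),
                    error = function(e) NULL)
    if (!is.null(fit)) lls[i] <- cox_loglik(fit$beta, X_tune, times_tune, events_tune)
  }
  if (all(is.na(lls))) stop("all ridge fits failed across the grid")
  best <- max(lls, na.rm = TRUE)
  lambda <- max(grid[!is.na(lls) & lls >= best - 1e-9])  # ties -> larger lambda
  list(lambda = lambda, tune_loglik = lls, grid = grid)
}

#' Breslow baseline cumulative hazard
#'
#' \eqn{H_0(t) = \sum_{t_i \le t} d_i / \sum_{j \in R(t_i)} e^{lp_j}}, a
#' non-decreasing step function with \eqn{H_0(0) = 0}.
#'
#' @param lp Linear predictors of the training data (same covariate coding
#'   as the fit).
#' @param times,events Training outcome.
#' @return List: `time` (event times), `hazard` (cumulative), and `fun`, a
#'   step function evaluating \eqn{H_0(t)}.
#' @export
breslow_baseline <- function(lp, times, events) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- as.numeric(events[ord]); w <- exp(lp[ord])
  first <- !duplicated(t_s)
  grp <- cumsum(first)
  S0 <- rev(cumsum(rev(w)))[first]
  d_g <- rowsum(e_s, grp, reorder = FALSE)[, 1]
  keep <- d_g > 0
  tg <- t_s[first][keep]
  H <- cumsum(d_g[keep] / S0[keep])
  fn <- if (length(tg)) stats::stepfun(tg, c(0, H)) else function(t) rep(0, length(t))
  list(time = tg, hazard = H, fun = fn)
}

#' Kaplan-Meier survival estimate
#'
#' Product-limit estimate (via [survival::survfit]).
#'
#' @param times,events Outcome vectors.
#' @return List: `time`, `surv`, and `fun`, a right-continuous step
#'   function with S(0) = 1.
#' @export
kaplan_meier <- function(times, events) {
  if (any(times < 0)) stop("negative survival times")
  sf <- survival::survfit(survival::Surv(times, events) ~ 1)
  fn <- stats::stepfun(sf$time, c(1, sf$surv))
  list(time = sf$time, surv = sf$surv, fun = fn)
}

#' Two-group log-rank test
#'
#' @param groups Two-level grouping vector.
#' @param times,events Outcome vectors.
#' @return List: `statistic` (chi-square, 1 df), `p_value`.
#' @export
logrank_test <- function(groups, times, events) {
  g <- as.factor(groups)
  if (nlevels(g) != 2L) stop("logrank_test requires exactly two groups")
  if (any(tabulate(g, 2L) == 0L)) stop("empty group")
  sd_ <- survival::survdiff(survival::Surv(times, events) ~ g)
  list(statistic = sd_$chisq,
       p_value = stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE))
}

#' SBP-140 screening rule
#'
#' Flags systolic blood pressure strictly above 140 mmHg.
#'
#' @param sbp Systolic blood pressure (mmHg).
#' @return 0/1 vector; `NA` SBP gives `NA` (excluded downstream).
#' @export
sbp140_score <- function(sbp) as.numeric(sbp > 140)
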
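# Evaluation statistics: Harrell's C, ten-year labels with the
# insufficient-follow-up exclusion, sensitivity/specificity with
# Clopper-Pearson intervals, category-free and threshold NRI, percentile
# bootstrap, the paired permutation non-inferiority test, decile
# calibration, threshold matching, and subgroup evaluation.

#' Harrell's concordance statistic
#'
#' Probability that a comparable pair (the shorter time is an event) is
#' ordered correctly by the risk score; score ties count 1/2. Computed via
#' [survival::concordance] (risk direction: higher score, shorter time).
#'
#' @param times,events Outcome vectors.
#' @param scores Risk scores (higher = riskier).
#' @param ci If `TRUE`, attach a percentile bootstrap CI.
#' @param B,seed Bootstrap settings.
#' @return The estimate, or with `ci` a list `estimate`/`ci_low`/`ci_high`.
#' @export
harrell_c <- function(times, events, scores, ci = FALSE, B = 1000L, seed = 1L) {
  est <- .cstat(times, events, scores)
  if (!ci) return(est)
  bs <- bootstrap_ci(function(idx) .cstat(times[idx], events[idx], scores[idx]),
                     n = length(times), B = B, seed = seed)
  list(estimate = est, ci_low = bs[1], ci_high = bs[2], ci_method = "bootstrap_percentile",
       n_effective = length(times))
}

.cstat <- function(times, events, scores) {
  .cstat_surv(survival::Surv(times, events), scores)
}

# risk-direction concordance on a prebuilt Surv object (hot path: the
# permutation test reuses one Surv across thousands of evaluations)
.cstat_surv <- function(y, scores) {
  as.numeric(survival::concordancefit(y, -scores)$concordance)
}

#' Ten-year outcome label
#'
#' Event within the horizon is 1; follow-up reaching the horizon without an
#' event is 0; censoring before the horizon without an event is excluded
#' (`NA`).
#'
#' @param time,event Outcome vectors (time in days by default).
#' @param horizon_days Horizon (ten years).
#' @return 0/1/`NA` vector.
#' @export
ten_year_label <- function(time, event, horizon_days = TEN_YEARS_DAYS) {
  ifelse(event == 1 & time <= horizon_days, 1,
         ifelse(time >= horizon_days, 0, NA_real_))
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' @param k Successes. @param n Trials. @param alpha Two-sided level.
#' @return `c(lo, hi)`.
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n) stop("need 0 <= k <= n, n >= 1")
  lo <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lo, hi)
}

#' Sensitivity and specificity at a threshold
#'
#' Computed on non-excluded subjects only (see [ten_year_label()]);
#' positive means score strictly above the threshold. Clopper-Pearson 95%
#' intervals.
#'
#' @param labels Ten-year labels (0/1/`NA`).
#' @param scores Risk scores.
#' @param threshold Decision threshold.
#' @return List of two `metric_result`s: `sensitivity`, `specificity`.
#' @export
sens_spec <- function(labels, scores, threshold) {
  keep <- !is.na(labels)
  lab <- labels[keep]; pos <- scores[keep] > threshold
  n1 <- sum(lab == 1); n0 <- sum(lab == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one event and one nonevent")
  k1 <- sum(pos & lab == 1); k0 <- sum(!pos & lab == 0)
  mk <- function(k, n) {
    ci <- clopper_pearson(k, n)
    list(estimate = k / n, ci_low = ci[1], ci_high = ci[2],
         ci_method = "clopper_pearson", n_effective = n)
  }
  list(sensitivity = mk(k1, n1), specificity = mk(k0, n0))
}

#' Category-free net reclassification improvement
#'
#' Event component: 100 * (P(new > ref | event) - P(new < ref | event));
#' nonevent component with the directions reversed; overall is their sum.
#' Exact score ties contribute zero.
#'
#' @param scores_ref,scores_new Paired risk scores.
#' @param labels Ten-year labels (excluded = `NA` dropped).
#' @return List `overall`/`event`/`nonevent`, in percent.
#' @export
cfnri <- function(scores_ref, scores_new, labels) {
  keep <- !is.na(labels)
  r <- scores_ref[keep]; s <- scores_new[keep]; lab <- labels[keep]
  if (!any(lab == 1) || !any(lab == 0)) stop("need both events and nonevents")
  up <- s > r; down <- s < r
  ev <- 100 * (mean(up[lab == 1]) - mean(down[lab == 1]))
  ne <- 100 * (mean(down[lab == 0]) - mean(up[lab == 0]))
  list(overall = ev + ne, event = ev, nonevent = ne)
}

#' Two-category NRI at a risk threshold
#'
#' As [cfnri()] but reclassification means crossing the threshold.
#'
#' @inheritParams cfnri
#' @param threshold Risk threshold defining the two categories.
#' @return List `overall`/`event`/`nonevent`, in percent.
#' @export
nri_at_threshold <- function(scores_ref, scores_new, labels, threshold) {
  cfnri(as.numeric(scores_ref > threshold), as.numeric(scores_new > threshold), labels)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subject indices with replacement; `statistic` receives the
#' index vector (so paired statistics resample pairs). Degenerate resamples
#' (statistic throws or returns `NA`) are redrawn, with the count recorded
#' in the `redrawn` attribute.
#'
#' @param statistic `function(idx)` returning a scalar.
#' @param n Number of subjects.
#' @param B Bootstrap iterations.
#' @param seed RNG seed.
#' @param alpha Two-sided level.
#' @return `c(lo, hi)` with attribute `redrawn`.
#' @export
bootstrap_ci <- function(statistic, n, B = 1000L, seed = 1L, alpha = 0.05) {
  set.seed(seed)
  vals <- numeric(B); redrawn <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      v <- tryCatch(statistic(idx), error = function(e) NA_real_)
      if (is.finite(v)) break
      redrawn <- redrawn + 1L
      if (redrawn > 10L * B) stop("statistic undefined on almost all resamples")
    }
    vals[b] <- v
  }
  out <- unname(stats::quantile(vals, c(alpha / 2, 1 - alpha / 2), type = 7))
  attr(out, "redrawn") <- redrawn
  out
}

#' Paired permutation test of non-inferiority and superiority of Harrell's C
#'
#' The observed statistic is \eqn{\Delta} = 100 (C(new) - C(ref)) in
#' percentage points. The null distribution exchanges the two scores within
#' each subject independently with probability 1/2 per permutation.
#' Superiority: one-sided p for H0 \eqn{\Delta \le 0}. Non-inferiority:
#' shift construction testing H0 \eqn{\Delta \le -margin}, i.e. the
#' permuted deltas are compared against \eqn{\Delta_{obs} + margin}.
#'
#' @param scores_ref,scores_new Paired risk scores on identical subjects.
#' @param times,events Outcome.
#' @param margin Non-inferiority margin in C percentage points.
#' @param n_perm Permutations.
#' @param seed RNG seed.
#' @return `noninferiority_result`: `delta`, `margin`, `p_noninferiority`,
#'   `p_superiority`, `n_permutations`.
#' @export
permutation_noninferiority <- function(scores_ref, scores_new, times, events,
                                       margin = 2.5, n_perm = 1000L, seed = 1L) {
  n <- length(times)
  stopifnot(length(scores_ref) == n, length(scores_new) == n)
  if (n_perm < 100L) warning("fewer than 100 permutations: p-values are coarse")
  y <- survival::Surv(times, events)
  c_ref <- .cstat_surv(y, scores_ref)
  c_new <- .cstat_surv(y, scores_new)
  delta <- 100 * (c_new - c_ref)
  set.seed(seed)
  perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    swap <- stats::runif(n) < 0.5
    a <- ifelse(swap, scores_new, scores_ref)
    bb <- ifelse(swap, scores_ref, scores_new)
    perm[b] <- 100 * (.cstat_surv(y, bb) - .cstat_surv(y, a))
  }
  p_sup <- (1 + sum(perm >= delta)) / (n_perm + 1)
  p_ni <- (1 + sum(perm >= delta + margin)) / (n_perm + 1)
  structure(list(delta = delta, margin = margin, p_noninferiority = p_ni,
                 p_superiority = p_sup, n_permutations = n_perm),
            class = "noninferiority_result")
}

#' Decile calibration of predicted ten-year risk
#'
#' Bins subjects by predicted-risk deciles (quintiles for small
#' subgroups), computes the observed ten-year event rate per bin among
#' non-excluded subjects, and regresses observed on predicted bin means by
#' ordinary least squares. Empty or single-subject duplicate bins are
#' merged with their neighbor.
#'
#' @param preds Predicted ten-year risks.
#' @param times,events Outcome.
#' @param bins Number of prediction bins (10 deciles by default).
#' @return `calibration_curve`: `predicted`, `observed`, `n` (per bin),
#'   `slope`, `intercept`, `mace` (mean absolute calibration error).
#' @export
calibration <- function(preds, times, events, bins = 10L) {
  labels <- ten_year_label(times, events)
  keep <- !is.na(labels) & !is.na(preds)
  p <- preds[keep]; lab <- labels[keep]
  if (length(p) < bins * 5L) stop("too few labelled subjects for ", bins, " bins")
  brk <- unique(stats::quantile(p, seq(0, 1, length.out = bins + 1L), type = 7))
  if (length(brk) < 3L) stop("predictions too discrete to bin")
  g <- cut(p, brk, include.lowest = TRUE)
  pred_bin <- tapply(p, g, mean)
  obs_bin <- tapply(lab, g, mean)
  n_bin <- tapply(lab, g, length)
  ok <- !is.na(pred_bin)
  pred_bin <- pred_bin[ok]; obs_bin <- obs_bin[ok]; n_bin <- n_bin[ok]
  fit <- stats::lm.fit(cbind(1, pred_bin), obs_bin)
  structure(list(predicted = as.numeric(pred_bin), observed = as.numeric(obs_bin),
                 n = as.integer(n_bin),
                 slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 mace = mean(abs(obs_bin - pred_bin))),
            class = "calibration_curve")
}

#' Match a risk threshold to a reference rule's operating point
#'
#' For a specificity target, returns the smallest threshold whose
#' specificity is at least the reference rule's (ties toward the larger
#' threshold); for a sensitivity target, the largest threshold whose
#' sensitivity is at least the reference's. `target = "fixed"` returns
#' `fixed` unchanged (the 10 percent predicted-risk threshold).
#'
#' @param ref_positive Logical vector: the reference rule's positives.
#' @param labels Ten-year labels.
#' @param scores Risk scores to threshold.
#' @param target `"sensitivity"`, `"specificity"` or `"fixed"`.
#' @param fixed Threshold returned in fixed mode (default 0.10).
#' @return The selected threshold.
#' @export
match_threshold <- function(ref_positive, labels, scores,
                            target = c("specificity", "sensitivity", "fixed"),
                            fixed = 0.10) {
  target <- match.arg(target)
  if (target == "fixed") return(fixed)
  keep <- !is.na(labels)
  lab <- labels[keep]; sc <- scores[keep]; rp <- ref_positive[keep]
  ref_val <- if (target == "sensitivity") mean(rp[lab == 1]) else mean(!rp[lab == 0])
  cand <- sort(unique(c(min(sc) - 1, sc)))
  metric <- vapply(cand, function(th) {
    pos <- sc > th
    if (target == "sensitivity") mean(pos[lab == 1]) else mean(!pos[lab == 0])
  }, numeric(1))
  ok <- metric >= ref_val - 1e-12
  if (!any(ok)) stop("target ", target, " of ", ref_val, " unattainable")
  # sensitivity is non-increasing in the threshold: take the largest
  # threshold still meeting the target; specificity is non-decreasing:
  # take the smallest (candidates are unique score values).
  if (target == "sensitivity") max(cand[ok]) else min(cand[ok])
}

#' Per-subgroup evaluation table
#'
#' @param df Cohort table with `time`, `event`.
#' @param scores Risk scores (ranking). @param preds Predicted risks
#'   (calibration). @param threshold Global operating threshold.
#' @param subgroups Named list of logical vectors.
#' @param small_bins Bins used when a subgroup is flagged small (< 500).
#' @return Data frame: one row per subgroup with n, events, C, sens, spec,
#'   calibration slope.
#' @export
subgroup_eval <- function(df, scores, preds, threshold, subgroups,
                          small_bins = 5L) {
  rows <- lapply(names(subgroups), function(nm) {
    sel <- subgroups[[nm]] & !is.na(scores)
    n <- sum(sel)
    if (n == 0) return(NULL)
    if (n < 50) warning("subgroup ", nm, " has fewer than 50 subjects")
    labels <- ten_year_label(df$time[sel], df$event[sel])
    cs <- .cstat(df$time[sel], df$event[sel], scores[sel])
    ss <- tryCatch(sens_spec(labels, scores[sel], threshold), error = function(e) NULL)
    cal <- tryCatch(calibration(preds[sel], df$time[sel], df$event[sel],
                                bins = if (n < 500) small_bins else 10L),
                    error = function(e) NULL)
    data.frame(subgroup = nm, n = n, events = sum(df$event[sel]),
               c_statistic = cs,
               sensitivity = if (is.null(ss)) NA_real_ else ss$sensitivity$estimate,
               specificity = if (is.null(ss)) NA_real_ else ss$specificity$estimate,
               calibration_slope = if (is.null(cal)) NA_real_ else cal$slope)
  })
  do.call(rbind, rows)
}
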
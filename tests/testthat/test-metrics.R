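test_that("Harrell's C matches the pair-enumeration oracle with ties and censoring", {
  expect_equal(harrell_c(c(1, 2, 3, 4), rep(1, 4), c(4, 3, 2, 1)), 1)
  expect_equal(harrell_c(c(1, 2, 3, 4), rep(1, 4), c(1, 2, 3, 4)), 0)
  # 6-subject toy with one censored subject and a score tie
  t <- c(2, 4, 1, 5, 3, 6); e <- c(1, 1, 1, 0, 1, 1); s <- c(5, 3, 5, 2, 4, 1)
  expect_equal(harrell_c(t, e, s), oracle_cindex(t, e, s))
  for (r in 1:200) {
    d <- rand_surv(15, seed = 1000 + r)
    expect_equal(harrell_c(d$times, d$events, d$scores),
                 oracle_cindex(d$times, d$events, d$scores), tolerance = 1e-12)
  }
})

test_that("ten-year labels implement the insufficient-follow-up exclusion", {
  yr <- 365.25
  expect_equal(ten_year_label(4 * yr, 1), 1)
  expect_true(is.na(ten_year_label(8 * yr, 0)))
  expect_equal(ten_year_label(11 * yr, 0), 0)
  expect_equal(ten_year_label(11 * yr, 1), 0)   # event after the horizon
  expect_equal(ten_year_label(8 * yr, 1), 1)
})

test_that("sensitivity/specificity are computed on labelled subjects with exact CIs", {
  lab <- c(rep(1, 4), rep(0, 6))
  sc <- c(0.9, 0.8, 0.7, 0.2, 0.1, 0.15, 0.05, 0.3, 0.25, 0.35)
  res <- sens_spec(lab, sc, 0.5)
  expect_equal(res$sensitivity$estimate, 3 / 4)
  expect_equal(res$specificity$estimate, 1)
  expect_equal(unname(c(res$sensitivity$ci_low, res$sensitivity$ci_high)),
               unname(clopper_pearson(3, 4)))
  # threshold below every score: sensitivity 1, specificity 0
  res2 <- sens_spec(lab, sc, -1)
  expect_equal(res2$sensitivity$estimate, 1)
  expect_equal(res2$specificity$estimate, 0)
  # excluded subjects are dropped
  lab3 <- c(lab, NA, NA)
  sc3 <- c(sc, 100, -100)
  res3 <- sens_spec(lab3, sc3, 0.5)
  expect_equal(res3$sensitivity$estimate, res$sensitivity$estimate)
  # hand-counted 20-subject table
  set.seed(30)
  lab4 <- rbinom(20, 1, 0.4); lab4[1] <- 1; lab4[2] <- 0
  sc4 <- runif(20)
  r4 <- sens_spec(lab4, sc4, 0.5)
  expect_equal(r4$sensitivity$estimate,
               sum(sc4 > 0.5 & lab4 == 1) / sum(lab4 == 1))
  expect_equal(r4$specificity$estimate,
               sum(sc4 <= 0.5 & lab4 == 0) / sum(lab4 == 0))
  expect_error(sens_spec(rep(1, 5), runif(5), 0.5), "nonevent")
})

test_that("Clopper-Pearson intervals satisfy the defining binomial tail equations", {
  expect_equal(clopper_pearson(0, 10)[1], 0)
  ci_full <- clopper_pearson(10, 10)
  expect_equal(ci_full[1], 0.025^(1 / 10), tolerance = 1e-10)
  expect_equal(ci_full[2], 1)
  # brute-force tail sums: P(X >= k | lo) = alpha/2, P(X <= k | hi) = alpha/2
  for (r in 1:100) {
    set.seed(r)
    n <- sample(5:40, 1); k <- sample(1:(n - 1), 1)
    ci <- clopper_pearson(k, n)
    up_tail <- sum(choose(n, k:n) * ci[1]^(k:n) * (1 - ci[1])^(n - (k:n)))
    lo_tail <- sum(choose(n, 0:k) * ci[2]^(0:k) * (1 - ci[2])^(n - (0:k)))
    expect_equal(up_tail, 0.025, tolerance = 1e-9)
    expect_equal(lo_tail, 0.025, tolerance = 1e-9)
  }
  expect_error(clopper_pearson(5, 0), "n >= 1")
})

test_that("category-free NRI matches enumeration and attains its formula bounds", {
  lab <- c(1, 1, 1, 0, 0, 0, 0, 0)
  ref <- c(1, 2, 3, 4, 5, 6, 7, 8)
  expect_equal(cfnri(ref, ref, lab), list(overall = 0, event = 0, nonevent = 0))
  # every event up, every nonevent down: (200, 100, 100)
  new_max <- ref + ifelse(lab == 1, 1, -1)
  expect_equal(cfnri(ref, new_max, lab), list(overall = 200, event = 100, nonevent = 100))
  for (r in 1:100) {
    set.seed(2000 + r)
    lab_r <- c(1, 0, rbinom(10, 1, 0.4))
    a <- runif(12); b <- a + sample(c(-0.1, 0, 0.1), 12, replace = TRUE)
    got <- cfnri(a, b, lab_r)
    want <- oracle_cfnri(a, b, lab_r)
    expect_equal(got$overall, unname(want["overall"]), tolerance = 1e-12)
    expect_equal(got$event, unname(want["event"]), tolerance = 1e-12)
    expect_equal(got$nonevent, unname(want["nonevent"]), tolerance = 1e-12)
    expect_true(abs(got$event) <= 100 && abs(got$nonevent) <= 100)
    expect_equal(got$overall, got$event + got$nonevent)
  }
})

test_that("threshold NRI reduces to two-category reclassification counting", {
  lab <- c(1, 1, 0, 0, 0)
  ref <- c(0.05, 0.04, 0.2, 0.01, 0.02)
  new <- c(0.15, 0.12, 0.05, 0.03, 0.25)
  got <- nri_at_threshold(ref, new, lab, 0.10)
  # both events cross up (+100); one nonevent down, one up -> 0
  expect_equal(got$event, 100)
  expect_equal(got$nonevent, 0)
  expect_equal(nri_at_threshold(ref, ref, lab, 0.10)$overall, 0)
  for (r in 1:100) {
    set.seed(3000 + r)
    lab_r <- c(1, 0, rbinom(10, 1, 0.4))
    a <- runif(12); b <- runif(12)
    got <- nri_at_threshold(a, b, lab_r, 0.5)
    want <- oracle_cfnri(as.numeric(a > 0.5), as.numeric(b > 0.5), lab_r)
    expect_equal(got$overall, unname(want["overall"]), tolerance = 1e-12)
  }
})

test_that("percentile bootstrap behaves sanely", {
  x <- 1:100
  ci <- bootstrap_ci(function(idx) mean(x[idx]), n = 100, B = 1000, seed = 2)
  expect_true(ci[1] < 50.5 && 50.5 < ci[2])
  ci_const <- bootstrap_ci(function(idx) 3.14, n = 50, B = 200, seed = 1)
  expect_equal(unname(ci_const[1]), unname(ci_const[2]))
  ci_a <- bootstrap_ci(function(idx) mean(x[idx]), n = 100, B = 300, seed = 7)
  ci_b <- bootstrap_ci(function(idx) mean(x[idx]), n = 100, B = 300, seed = 7)
  expect_identical(ci_a, ci_b)
})

test_that("the paired permutation test is reproducible and null-centred", {
  set.seed(17)
  n <- 400
  u <- rnorm(n)
  t <- rexp(n) / exp(u); cens <- quantile(t, 0.7)
  e <- as.integer(t <= cens); tt <- pmin(t, cens)
  sa <- u + rnorm(n, 0, 0.7)
  r1 <- permutation_noninferiority(sa, sa, tt, e, n_perm = 200, seed = 3)
  expect_equal(r1$delta, 0)
  expect_gte(r1$p_superiority, 0.4)
  expect_lt(r1$p_noninferiority, 0.05)
  r2 <- permutation_noninferiority(sa, sa, tt, e, n_perm = 200, seed = 3)
  expect_identical(r1, r2)
  expect_warning(permutation_noninferiority(sa, sa, tt, e, n_perm = 50, seed = 1),
                 "100 permutations")
})

test_that("decile calibration recovers exact slopes and matches closed-form OLS", {
  yr <- 365.25
  # 10 bins, within-bin constant predictions, observed = predicted exactly
  p_levels <- seq(0.05, 0.5, by = 0.05)
  preds <- rep(p_levels, each = 40)
  n <- length(preds)
  lab <- unlist(lapply(p_levels, function(p) {
    k <- round(40 * p); c(rep(1, k), rep(0, 40 - k))
  }))
  times <- ifelse(lab == 1, 5 * yr, 11 * yr)
  cal <- calibration(preds, times, lab, bins = 10)
  expect_equal(cal$slope, 1, tolerance = 1e-9)
  expect_lt(cal$mace, 1e-12)
  # predicted exactly double the observed: slope 1/2 through the origin
  cal2 <- calibration(2 * preds, times, lab, bins = 10)
  expect_equal(cal2$slope, 0.5, tolerance = 1e-9)
  expect_equal(cal2$intercept, 0, tolerance = 1e-9)
  # closed-form least squares on the bin means
  set.seed(9)
  preds3 <- runif(600)
  lab3 <- rbinom(600, 1, preds3)
  times3 <- ifelse(lab3 == 1, 3 * yr, 12 * yr)
  cal3 <- calibration(preds3, times3, lab3, bins = 10)
  ols <- oracle_ols(cal3$predicted, cal3$observed)
  expect_equal(cal3$slope, unname(ols["slope"]), tolerance = 1e-10)
  expect_equal(cal3$intercept, unname(ols["intercept"]), tolerance = 1e-10)
  # invariant to subject order
  perm <- sample(600)
  cal4 <- calibration(preds3[perm], times3[perm], lab3[perm], bins = 10)
  expect_equal(cal4$slope, cal3$slope, tolerance = 1e-12)
})

test_that("threshold matching hits the reference operating point", {
  set.seed(40)
  lab <- c(rep(1, 30), rep(0, 70))
  sc <- c(rnorm(30, 1), rnorm(70))
  ref_pos <- c(rbinom(30, 1, 0.6), rbinom(70, 1, 0.35)) == 1
  for (target in c("sensitivity", "specificity")) {
    th <- match_threshold(ref_pos, lab, sc, target = target)
    ref_val <- if (target == "sensitivity") mean(ref_pos[lab == 1]) else mean(!ref_pos[lab == 0])
    got <- sens_spec(lab, sc, th)
    attained <- if (target == "sensitivity") got$sensitivity$estimate else got$specificity$estimate
    expect_gte(attained, ref_val)
    # exhaustive scan: no better-matching threshold exists
    cand <- sort(unique(c(min(sc) - 1, sc)))
    vals <- vapply(cand, function(t0) {
      pos <- sc > t0
      if (target == "sensitivity") mean(pos[lab == 1]) else mean(!pos[lab == 0])
    }, numeric(1))
    ok <- cand[vals >= ref_val]
    expect_equal(th, if (target == "sensitivity") max(ok) else min(ok))
  }
  # reference specificity 0 -> threshold below every score
  th0 <- match_threshold(rep(TRUE, 100), lab, sc, target = "specificity")
  expect_lt(th0, min(sc))
  # fixed mode returns the 10% threshold untouched
  expect_equal(match_threshold(ref_pos, lab, sc, target = "fixed"), 0.10)
})

test_that("subgroup evaluation is consistent with global metrics", {
  set.seed(50)
  n <- 1200
  yr <- 365.25
  sc <- rnorm(n)
  t_years <- rexp(n) / (0.03 * exp(0.5 * sc))
  cens <- runif(n, 0, 14)
  df <- data.frame(time = pmin(t_years, cens) * yr,
                   event = as.integer(t_years <= cens))
  preds <- 1 - exp(-0.3 * exp(0.5 * sc))
  grp <- rep(c(TRUE, FALSE), length.out = n)
  tab <- subgroup_eval(df, sc, preds, 0, list(all = rep(TRUE, n), a = grp, b = !grp))
  expect_equal(tab$c_statistic[tab$subgroup == "all"], harrell_c(df$time, df$event, sc))
  expect_equal(sum(tab$events[tab$subgroup %in% c("a", "b")]),
               sum(df$event))
})
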
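test_that("unpenalized fit matches a grid-search oracle on toy data", {
  set.seed(2)
  n <- 20
  x <- rep(c(0, 1), each = 10)
  t <- c(rexp(10, 0.5), rexp(10, 1.5))
  e <- rbinom(n, 1, 0.8); e[1] <- 1
  fit <- fit_cox_ridge(matrix(x, ncol = 1), t, e, lambda = 0)
  # brute-force maximization of the Breslow partial likelihood over a grid
  grid <- seq(-3, 3, by = 1e-3)
  ll <- vapply(grid, function(b) ppgsurv:::cox_loglik(b, matrix(x, ncol = 1), t, e),
               numeric(1))
  expect_lt(abs(fit$beta - grid[which.max(ll)]), 1e-3)
  # and the independent Newton solver in survival agrees
  cph <- survival::coxph(survival::Surv(t, e) ~ x, ties = "breslow")
  expect_equal(unname(fit$beta), unname(coef(cph)), tolerance = 1e-6)
})

test_that("an overwhelming ridge penalty shrinks coefficients to zero", {
  set.seed(4)
  n <- 100
  X <- matrix(rnorm(2 * n), n, 2)
  t <- rexp(n); e <- rbinom(n, 1, 0.6); e[1] <- 1
  fit <- fit_cox_ridge(X, t, e, lambda = 1e6)
  expect_true(all(abs(fit$beta) < 1e-3))
})

test_that("the fit recovers a known coefficient from simulated data", {
  set.seed(10)
  n <- 10000
  x <- rnorm(n)
  t <- rexp(n) / (0.02 * exp(0.7 * x))
  cens <- runif(n, 0, quantile(t, 0.35))
  e <- as.integer(t <= cens); tt <- pmin(t, cens)
  fit <- fit_cox_ridge(matrix(x, ncol = 1), tt, e, lambda = 0)
  expect_gt(fit$beta, 0.6)
  expect_lt(fit$beta, 0.8)
})

test_that("degenerate designs are rejected", {
  set.seed(5)
  X <- cbind(rnorm(30), 1)
  expect_error(fit_cox_ridge(X, rexp(30), rbinom(30, 1, .8), 0), "constant")
  expect_error(fit_cox_ridge(matrix(rnorm(30), ncol = 30), rexp(1), 1, 0), "more subjects")
})

test_that("ridge tuning picks the tune-likelihood maximizer with ties to larger lambda", {
  set.seed(4)
  n <- 3000
  X <- matrix(rnorm(n * 3), n, 3)
  lp <- X %*% c(0.8, -0.5, 0.3)
  t <- rexp(n) / (0.05 * exp(lp))
  cens <- runif(n, 0, quantile(t, .5))
  e <- as.integer(t <= cens); tt <- pmin(t, cens)
  i1 <- 1:2000; i2 <- 2001:3000
  grid <- c(0.01, 0.1, 1, 10, 100)
  sel <- tune_ridge(X[i1, ], tt[i1], e[i1], X[i2, ], tt[i2], e[i2], grid)
  expect_equal(sel$lambda, grid[which.max(sel$tune_loglik)])
  # with this much signal the heaviest penalty cannot win
  expect_lt(sel$lambda, max(grid))
  # single-value grid is returned untouched
  expect_equal(tune_ridge(X[i1, ], tt[i1], e[i1], X[i2, ], tt[i2], e[i2], 5)$lambda, 5)
  # exact ties break toward the larger penalty
  sel2 <- tune_ridge(X[i1, ], tt[i1], e[i1], X[i2, ], tt[i2], e[i2], c(1, 1))
  expect_equal(sel2$lambda, 1)
})

test_that("Breslow baseline hazard is a proper step function agreeing with KM at null", {
  set.seed(3)
  n <- 1000
  t <- rexp(n, 0.1); cens <- runif(n, 0, 15)
  e <- as.integer(t <= cens); tt <- pmin(t, cens)
  bl <- breslow_baseline(rep(0, n), tt, e)
  expect_equal(bl$fun(0), 0)
  expect_true(all(diff(bl$hazard) >= 0))
  expect_equal(bl$fun(min(tt[e == 1]) / 2), 0)   # no events yet -> H0 = 0
  km <- kaplan_meier(tt, e)
  tg <- seq(0.5, 8, by = 0.5)
  expect_lt(max(abs((1 - exp(-bl$fun(tg))) - (1 - km$fun(tg)))), 0.02)
})

test_that("Kaplan-Meier matches hand product-limit arithmetic", {
  # times {1 event, 2 censored, 3 event}: S(1) = 2/3, S(3) = 0
  km <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$fun(1), 2 / 3)
  expect_equal(km$fun(3), 0)
  # no events: S identically 1
  km2 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km2$fun(c(0.5, 1.5, 4)) == 1))
  # all events, distinct times: complement of the ECDF
  tset <- c(2, 5, 7, 11)
  km3 <- kaplan_meier(tset, rep(1, 4))
  expect_equal(km3$fun(tset), 1 - seq_len(4) / 4)
  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank test matches hand arithmetic and handles degenerate input", {
  g <- c(1, 1, 1, 2, 2, 2)
  t <- c(1, 3, 5, 2, 4, 6)
  e <- c(1, 1, 0, 1, 1, 1)
  res <- logrank_test(g, t, e)
  expect_equal(res$statistic, oracle_logrank(g, t, e), tolerance = 1e-10)
  expect_equal(res$p_value, pchisq(res$statistic, 1, lower.tail = FALSE))
  # duplicated data in both groups: no difference
  t2 <- rep(c(1, 2, 3), 2); e2 <- rep(c(1, 0, 1), 2); g2 <- rep(1:2, each = 3)
  expect_lt(logrank_test(g2, t2, e2)$statistic, 1e-10)
  expect_error(logrank_test(rep(1, 4), rexp(4), rep(1, 4)), "two groups")
})

test_that("ten-year risk predictions respect the survival identity", {
  set.seed(6)
  n <- 2000
  d <- data.frame(id = 1:n, age = rnorm(n, 57, 8), sex = rbinom(n, 1, .5),
                  smoking = rbinom(n, 1, .4))
  lp <- 0.5 * scale(d$age)[, 1] + 0.3 * d$sex
  t_years <- rexp(n) / (0.01 * exp(lp))
  cens <- runif(n, 0, 14)
  d$event <- as.integer(t_years <= cens)
  d$time <- pmin(t_years, cens) * 365.25
  i1 <- 1:1400; i2 <- 1401:2000
  m <- fit_feature_set("metadata", d[i1, ], d[i2, ], lambda_grid = c(0.1, 1))
  p <- predict_10yr_risk(m, d)
  expect_true(all(p$p10 > 0 & p$p10 < 1))
  # monotone in the linear predictor
  o <- order(p$lp)
  expect_true(all(diff(p$p10[o]) >= 0))
  # the reference subject (lp = 0) gets 1 - exp(-H0(10y))
  H10 <- m$baseline$fun(10 * 365.25)
  ref_row <- d[1, ]
  for (f in m$spec$features) ref_row[[f]] <- m$spec$scaler[[f]]$mean
  pr <- predict_10yr_risk(m, ref_row)
  expect_equal(pr$p10, 1 - exp(-H10), tolerance = 1e-10)
})

test_that("SBP-140 uses the strict above-140 convention", {
  expect_equal(sbp140_score(c(139, 140, 141)), c(0, 0, 1))
  expect_true(is.na(sbp140_score(NA)))
})
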
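# Independent brute-force / closed-form oracles used across the suite.
# These are deliberately written as naive loops and textbook formulas,
# sharing no code with the package implementations they check.

# Harrell's C by full pair enumeration. Comparable: the shorter time is an
# event (an event tied with a censoring time counts, the censored subject
# surviving longer); tied event times are not comparable. Score ties 1/2.
oracle_cindex <- function(times, events, scores) {
  n <- length(times)
  num <- 0; den <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      ti <- times[i]; tj <- times[j]; ei <- events[i]; ej <- events[j]
      if (ti < tj && ei == 1) { s <- i; l <- j }
      else if (tj < ti && ej == 1) { s <- j; l <- i }
      else if (ti == tj && ei != ej) { if (ei == 1) { s <- i; l <- j } else { s <- j; l <- i } }
      else next
      den <- den + 1
      if (scores[s] > scores[l]) num <- num + 1
      else if (scores[s] == scores[l]) num <- num + 0.5
    }
  }
  num / den
}

# category-free NRI by explicit counting
oracle_cfnri <- function(ref, new, labels) {
  keep <- !is.na(labels)
  ref <- ref[keep]; new <- new[keep]; lab <- labels[keep]
  up_e <- 0; dn_e <- 0; n_e <- 0; up_n <- 0; dn_n <- 0; n_n <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      n_e <- n_e + 1
      if (new[i] > ref[i]) up_e <- up_e + 1 else if (new[i] < ref[i]) dn_e <- dn_e + 1
    } else {
      n_n <- n_n + 1
      if (new[i] > ref[i]) up_n <- up_n + 1 else if (new[i] < ref[i]) dn_n <- dn_n + 1
    }
  }
  ev <- 100 * (up_e - dn_e) / n_e
  ne <- 100 * (dn_n - up_n) / n_n
  c(overall = ev + ne, event = ev, nonevent = ne)
}

# two-group log-rank chi-square from the textbook observed-minus-expected
# and hypergeometric-variance sums
oracle_logrank <- function(groups, times, events) {
  g <- as.integer(as.factor(groups))
  evt <- sort(unique(times[events == 1]))
  OE <- 0; V <- 0
  for (t in evt) {
    at_risk <- times >= t
    n1 <- sum(at_risk & g == 1); n2 <- sum(at_risk & g == 2); nn <- n1 + n2
    d1 <- sum(times == t & events == 1 & g == 1)
    d <- sum(times == t & events == 1)
    OE <- OE + d1 - d * n1 / nn
    if (nn > 1) V <- V + d * (n1 / nn) * (1 - n1 / nn) * (nn - d) / (nn - 1)
  }
  OE^2 / V
}

# average ranks computed by hand (no rank())
oracle_ranks <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- sum(x < x[i])
    ties <- sum(x == x[i])
    r[i] <- less + (ties + 1) / 2
  }
  r
}

# Spearman rho from the definitional Pearson-on-ranks sums
oracle_spearman <- function(x, y) {
  rx <- oracle_ranks(x); ry <- oracle_ranks(y)
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# closed-form simple least squares of y on x
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# pointwise linear interpolation written independently of approx()
oracle_interp <- function(t_in, y_in, t_out) {
  out <- numeric(length(t_out))
  for (k in seq_along(t_out)) {
    t <- t_out[k]
    if (t <= t_in[1]) { out[k] <- y_in[1]; next }
    if (t >= t_in[length(t_in)]) { out[k] <- y_in[length(y_in)]; next }
    i <- max(which(t_in <= t))
    w <- (t - t_in[i]) / (t_in[i + 1] - t_in[i])
    out[k] <- (1 - w) * y_in[i] + w * y_in[i + 1]
  }
  out
}

# a clean two-bump pulse on the 100-sample device grid
two_gauss_pulse <- function(p1 = 0.15, p2 = 0.40, a2 = 0.6, depth = 0.15,
                            pulse_rate = 60) {
  u <- (0:99) / 99
  y <- exp(-(u - p1)^2 / (2 * 0.05^2)) + a2 * exp(-(u - p2)^2 / (2 * 0.06^2)) -
    depth * exp(-(u - (p1 + p2) / 2)^2 / (2 * 0.03^2))
  raw_pulse_wave(y, pulse_rate)
}

# small random survival data set
rand_surv <- function(n, seed, score_levels = 5, time_levels = 8, p_event = 0.6) {
  set.seed(seed)
  repeat {
    t <- sample(seq_len(time_levels), n, replace = TRUE)
    e <- stats::rbinom(n, 1, p_event)
    s <- sample(seq_len(score_levels), n, replace = TRUE)
    if (sum(e) >= 1) return(list(times = t, events = e, scores = s))
  }
}
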
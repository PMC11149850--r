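#' Tape-speed augmentation parameters
#'
#' @param sigma Per-step volatility of the latent log tape speed
#'   (dimensionless, >= 0). 0 disables the warp.
#' @param seed Optional integer seed used when no RNG function is supplied.
#' @return A `tape_speed_params` object.
#' @export
tape_speed_params <- function(sigma = 0.05, seed = NULL) {
  if (!is.finite(sigma) || sigma < 0) stop("sigma must be >= 0")
  structure(list(sigma = sigma, seed = seed), class = "tape_speed_params")
}

#' Brownian tape-speed time warp
#'
#' Random monotone time warp used only while training the feature
#' extractor. A latent log tape speed follows a Brownian random walk
#' W_k (increments N(0, sigma^2), W_1 = 0); warped times are the cumulative
#' sum of exp(W_k), rescaled so the first warped time is 0 and the last
#' equals the original duration. The wave is then linearly interpolated at
#' the warped times, which pins both endpoints, preserves landmark order
#' (the warp is strictly increasing) and keeps values inside the input
#' range. sigma = 0 reproduces the input exactly.
#'
#' @param wave A `uniform_pulse_wave` (normalized).
#' @param params A [tape_speed_params()].
#' @param rng Optional function(n) returning n standard normal draws; when
#'   missing, R's RNG is used (seeded from `params$seed` if set).
#' @return The warped wave, same class and length.
#' @export
brownian_tape_speed <- function(wave, params, rng = NULL) {
  if (!inherits(params, "tape_speed_params")) stop("params must be tape_speed_params")
  x <- wave$samples
  n <- length(x)
  if (params$sigma == 0 || n < 3) return(wave)
  if (is.null(rng)) {
    if (!is.null(params$seed)) set.seed(params$seed)
    z <- stats::rnorm(n - 1L)
  } else z <- rng(n - 1L)
  w <- cumsum(c(0, params$sigma * z[-1L]))   # W_1 = 0
  tau <- cumsum(exp(w))                       # length n-1 speeds -> n times
  tau <- c(0, tau)
  tau <- tau / tau[n] * (n - 1)               # rescale to original duration (grid units)
  wave$samples <- stats::approx(seq_len(n) - 1, x, xout = tau, rule = 2)$y
  wave
}

# Warp every row of a padded batch in place (training-time only).
# rng_z: function(n) giving standard normals, so one seeded stream serves
# the whole batch.
augment_batch <- function(values, lengths, sigma, rng_z) {
  if (sigma == 0) return(values)
  p <- tape_speed_params(sigma)
  for (i in seq_along(lengths)) {
    n <- lengths[i]
    if (n < 3) next
    w <- structure(list(samples = values[i, seq_len(n)], dt_ms = PPG_DT_MS,
                        pulse_period_ms = (n - 1) * PPG_DT_MS),
                   class = "uniform_pulse_wave")
    values[i, seq_len(n)] <- brownian_tape_speed(w, p, rng = rng_z)$samples
  }
  values
}
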
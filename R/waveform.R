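# Grid step of the uniform time axis, in milliseconds. Clinical pulse-trace
# devices store the summarized pulse as 100 samples per beat irrespective of
# heart rate; resampling restores a common physical time base.
PPG_DT_MS <- 18.2

#' Construct a raw summarized pulse wave
#'
#' A raw pulse wave is the device-summarized single beat: exactly 100
#' amplitude samples (arbitrary device units) spanning one pulse period,
#' together with the pulse rate measured during acquisition.
#'
#' @param samples Numeric vector of exactly 100 finite amplitude values.
#' @param pulse_rate_bpm Pulse rate in beats per minute, in (20, 250).
#' @return An object of class `raw_pulse_wave`.
#' @export
raw_pulse_wave <- function(samples, pulse_rate_bpm) {
  samples <- as.numeric(samples)
  if (length(samples) != 100L) {
    stop("a raw pulse wave must have exactly 100 samples, got ", length(samples))
  }
  if (!all(is.finite(samples))) stop("raw pulse wave contains non-finite samples")
  if (!is.finite(pulse_rate_bpm) || pulse_rate_bpm <= 20 || pulse_rate_bpm >= 250) {
    stop("pulse_rate_bpm must lie in (20, 250), got ", pulse_rate_bpm)
  }
  structure(list(samples = samples, pulse_rate_bpm = as.numeric(pulse_rate_bpm)),
            class = "raw_pulse_wave")
}

#' Resample a raw pulse onto the uniform 18.2 ms grid
#'
#' The 100 raw samples are assumed evenly spread over one pulse period
#' (first sample at t = 0, spacing period/99 by default, endpoints
#' inclusive). Linear interpolation maps them onto the fixed grid
#' t_k = 18.2 ms * k for k = 0..floor(period/18.2), so the output length
#' varies with pulse rate: slower pulses give longer series.
#'
#' @param raw A [raw_pulse_wave()].
#' @param spacing_divisor Number of inter-sample intervals the 100 samples
#'   span; 99 (default) means both pulse endpoints are included.
#' @return An object of class `uniform_pulse_wave` with fields `samples`,
#'   `dt_ms` and `pulse_period_ms`.
#' @export
resample_to_uniform <- function(raw, spacing_divisor = 99) {
  if (!inherits(raw, "raw_pulse_wave")) raw <- raw_pulse_wave(raw$samples, raw$pulse_rate_bpm)
  period_ms <- 60000 / raw$pulse_rate_bpm
  t_in <- (0:99) * (period_ms / spacing_divisor)
  n_out <- floor(period_ms / PPG_DT_MS) + 1L
  t_out <- (seq_len(n_out) - 1L) * PPG_DT_MS
  # rule = 2: the last grid point can sit just beyond t_in[100] when the
  # divisor is 100; clamp to the final sample value.
  y <- stats::approx(t_in, raw$samples, xout = t_out, rule = 2)$y
  structure(list(samples = y, dt_ms = PPG_DT_MS, pulse_period_ms = period_ms),
            class = "uniform_pulse_wave")
}

#' Min-max normalize a uniform pulse wave to [0, 1]
#'
#' Device units are arbitrary, so each wave is affinely rescaled to
#' min 0 / max 1 before modelling. Flat waves carry no morphology and are
#' rejected.
#'
#' @param wave A `uniform_pulse_wave`.
#' @return The wave with `samples` rescaled to [0, 1]; idempotent.
#' @export
normalize_amplitude <- function(wave) {
  x <- wave$samples
  rng <- range(x)
  if (!all(is.finite(rng))) stop("non-finite samples in wave")
  if (rng[2] <= rng[1]) stop("flat wave (max == min): record rejected")
  wave$samples <- (x - rng[1]) / (rng[2] - rng[1])
  wave
}

#' Zero-pad a list of uniform pulse waves into a rectangular batch
#'
#' @param waves List of `uniform_pulse_wave` objects.
#' @param L Common length, or `"auto"` for the maximum valid length.
#' @param ids Optional row identifiers.
#' @return A `padded_batch`: `values` (n x L matrix, zeros beyond each row's
#'   valid length), `lengths` (valid length per row) and `ids`.
#' @export
pad_batch <- function(waves, L = "auto", ids = NULL) {
  lens <- vapply(waves, function(w) length(w$samples), integer(1))
  if (identical(L, "auto")) L <- max(lens)
  L <- as.integer(L)
  if (any(lens > L)) stop("L = ", L, " is smaller than the longest wave (", max(lens), ")")
  n <- length(waves)
  values <- matrix(0, n, L)
  for (i in seq_len(n)) values[i, seq_len(lens[i])] <- waves[[i]]$samples
  if (is.null(ids)) ids <- seq_len(n)
  structure(list(values = values, lengths = lens, ids = ids), class = "padded_batch")
}

#' Recover the individual waves from a padded batch
#'
#' @param batch A `padded_batch`.
#' @param dt_ms Grid step to stamp on the recovered waves.
#' @return List of `uniform_pulse_wave` objects (exact round trip of
#'   [pad_batch()]).
#' @export
unpad_batch <- function(batch, dt_ms = PPG_DT_MS) {
  lapply(seq_along(batch$lengths), function(i) {
    n <- batch$lengths[i]
    structure(list(samples = batch$values[i, seq_len(n)], dt_ms = dt_ms,
                   pulse_period_ms = (n - 1) * dt_ms),
              class = "uniform_pulse_wave")
  })
}

#' Read raw pulse waves from CSV
#'
#' Expected columns: `id`, `pulse_rate_bpm`, `s000` .. `s099`.
#'
#' @param path CSV file path.
#' @return List with `ids` and `waves` (list of `raw_pulse_wave`).
#' @export
read_waveform_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  scols <- sprintf("s%03d", 0:99)
  missing <- setdiff(c("id", "pulse_rate_bpm", scols), names(df))
  if (length(missing)) stop("waveform CSV missing columns: ", paste(missing, collapse = ", "))
  waves <- lapply(seq_len(nrow(df)), function(i) {
    raw_pulse_wave(as.numeric(df[i, scols]), df$pulse_rate_bpm[i])
  })
  list(ids = df$id, waves = waves)
}

#' Write raw pulse waves to CSV
#'
#' @param ids Identifiers, one per wave.
#' @param waves List of `raw_pulse_wave`.
#' @param path Output CSV path.
#' @export
write_waveform_csv <- function(ids, waves, path) {
  m <- t(vapply(waves, function(w) w$samples, numeric(100)))
  colnames(m) <- sprintf("s%03d", 0:99)
  df <- data.frame(id = ids,
                   pulse_rate_bpm = vapply(waves, function(w) w$pulse_rate_bpm, numeric(1)),
                   m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Preprocess a cohort's raw waves end to end: resample, normalize, pad.
# Waves failing validation (flat after resampling) are dropped with a log.
#' Preprocess raw pulse waves into a padded batch
#'
#' Resamples each wave to the uniform 18.2 ms grid, min-max normalizes, and
#' zero-pads to a rectangular batch. Invalid records (flat waveforms) are
#' dropped and reported in the `excluded` attribute.
#'
#' @param waves List of `raw_pulse_wave`.
#' @param ids Identifiers, one per wave.
#' @param L Target padded length or `"auto"`.
#' @return A `padded_batch` with attribute `excluded` (data frame id/reason).
#' @export
preprocess_waves <- function(waves, ids = seq_along(waves), L = "auto") {
  out <- vector("list", length(waves))
  bad <- character(0); bad_ids <- c()
  for (i in seq_along(waves)) {
    res <- tryCatch(normalize_amplitude(resample_to_uniform(waves[[i]])),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      bad <- c(bad, res); bad_ids <- c(bad_ids, ids[i]); out[[i]] <- NULL
    } else out[[i]] <- res
  }
  keep <- !vapply(out, is.null, logical(1))
  batch <- pad_batch(out[keep], L = L, ids = ids[keep])
  attr(batch, "excluded") <- data.frame(id = bad_ids, reason = bad,
                                        stringsAsFactors = FALSE)
  batch
}
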
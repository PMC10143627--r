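#' Per-second EEG band powers
#'
#' Splits the signal into non-overlapping 1 s epochs (matching the ~1 Hz
#' output cadence of consumer single-channel headsets), applies a Hann window
#' and a periodogram per epoch, and integrates the periodogram over each
#' band's closed frequency range (see [eeg_bands()]). A trailing partial
#' epoch is dropped. Powers are unitless magnitudes.
#'
#' @param signal `raw_signal` (EEG) or numeric vector.
#' @param fs_hz sampling rate; taken from the signal when omitted. Must be at
#'   least 100 Hz so the 31-50 Hz gamma band is resolvable.
#' @return Object of class `band_power_series`: list with `epoch_times_s`
#'   (epoch start times, 1 Hz grid) and `powers` (matrix, epochs x 7 bands).
#' @export
band_powers <- function(signal, fs_hz = NULL) {
  if (inherits(signal, "raw_signal")) {
    if (is.null(fs_hz)) fs_hz <- signal$fs_hz
    x <- signal$values
  } else {
    x <- as.numeric(signal)
    stop_if_not(!is.null(fs_hz), "fs_hz required for a bare numeric signal")
  }
  stop_if_not(fs_hz >= 100, "sampling rate too low to resolve the 31-50 Hz band")
  nper <- floor(fs_hz)
  n_ep <- floor(length(x) / nper)
  stop_if_not(n_ep >= 1, "signal must be at least 1 s long")

  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))
  freqs <- (seq_len(nper) - 1) * fs_hz / nper
  b <- eeg_bands()
  # periodogram bin -> band assignment (closed ranges, first half-spectrum)
  half <- freqs <= fs_hz / 2
  bin_band <- rep(NA_integer_, nper)
  for (i in seq_len(nrow(b))) {
    bin_band[half & freqs >= b$f_lo[i] & freqs <= b$f_hi[i]] <- i
  }

  pw <- matrix(0, nrow = n_ep, ncol = nrow(b),
               dimnames = list(NULL, b$band))
  for (e in seq_len(n_ep)) {
    seg <- x[((e - 1) * nper + 1):(e * nper)] * hann
    P <- Mod(stats::fft(seg))^2 / nper
    for (i in seq_len(nrow(b))) {
      pw[e, i] <- sum(P[which(bin_band == i)])
    }
  }
  structure(list(epoch_times_s = seq_len(n_ep) - 1, powers = pw),
            class = "band_power_series")
}

new_index_series <- function(name, times_s, values) {
  structure(list(name = name, times_s = times_s, values = as.numeric(values)),
            class = "index_series")
}

#' Surrogate Attention and Meditation indexes
#'
#' The proprietary headset Attention/Meditation algorithm is not public; its
#' published characterization is that Attention emphasizes the beta band and
#' Meditation the alpha band. This documented surrogate therefore uses the
#' relative beta and alpha power shares scaled to 0-100:
#' `att = 100 * (low_beta + high_beta) / T` and
#' `med = 100 * (low_alpha + high_alpha) / T`, with `T` the total power over
#' all seven bands. Epochs with zero total power are undefined (`NA`), not 0.
#' Their difference, Attention - Meditation, is the arousal index and is
#' bounded in `[-100, 100]`.
#'
#' @param bp a `band_power_series`.
#' @return list of two `index_series`: `att` ("attention_surrogate") and
#'   `med` ("meditation_surrogate").
#' @export
surrogate_attention_meditation <- function(bp) {
  stop_if_not(inherits(bp, "band_power_series"), "bp must be a band_power_series")
  p <- bp$powers
  total <- rowSums(p)
  att <- ifelse(total > 0, 100 * (p[, "low_beta"] + p[, "high_beta"]) / total, NA_real_)
  med <- ifelse(total > 0, 100 * (p[, "low_alpha"] + p[, "high_alpha"]) / total, NA_real_)
  list(att = new_index_series("attention_surrogate", bp$epoch_times_s, att),
       med = new_index_series("meditation_surrogate", bp$epoch_times_s, med))
}

#' Attention minus Meditation arousal series
#'
#' Convenience wrapper: the difference of the two surrogate indexes, in
#' `[-100, 100]` with neutral point 0; high values indicate high arousal.
#'
#' @param bp a `band_power_series`.
#' @return `index_series` named "att_minus_med".
#' @export
att_minus_med <- function(bp) {
  am <- surrogate_attention_meditation(bp)
  new_index_series("att_minus_med", am$att$times_s, am$att$values - am$med$values)
}

#' High-beta / high-alpha band-power ratio
#'
#' Per-epoch ratio `high_beta / (high_alpha + epsilon)`; a high value
#' indicates a high arousal level (alert, excited), a low value a relaxed yet
#' concentrated state. (The source literature's prose once inverts which band
#' is the denominator; the ratio implemented is the named one, high-beta over
#' high-alpha, consistent with "high value = high arousal".) The epsilon
#' guard keeps the ratio defined when high-alpha power is zero.
#'
#' @param bp a `band_power_series`.
#' @param epsilon denominator guard.
#' @return `index_series` named "hb_ha_ratio", values >= 0.
#' @export
hbeta_halpha_ratio <- function(bp, epsilon = 1e-12) {
  stop_if_not(inherits(bp, "band_power_series"), "bp must be a band_power_series")
  p <- bp$powers
  new_index_series("hb_ha_ratio", bp$epoch_times_s,
                   p[, "high_beta"] / (p[, "high_alpha"] + epsilon))
}

#' Raw band-power index series (delta, theta, ...)
#'
#' @param bp a `band_power_series`.
#' @param band one of the seven band names.
#' @return `index_series` carrying that band's per-epoch power.
#' @export
band_index <- function(bp, band) {
  stop_if_not(inherits(bp, "band_power_series"), "bp must be a band_power_series")
  stop_if_not(band %in% band_names(), "unknown EEG band: %s", band)
  new_index_series(band, bp$epoch_times_s, bp$powers[, band])
}

#' Trailing moving average of a 1 Hz index series
#'
#' Causal smoothing over the last `window_s` samples; the first
#' `window_s - 1` samples use the expanding prefix mean, so no future samples
#' are used and the output has the same length as the input. Undefined
#' (`NA`) inputs are excluded from each mean; a window with no defined sample
#' yields `NA`.
#'
#' @param series an `index_series` (or numeric vector).
#' @param window_s window length in samples at 1 Hz (default 15 s).
#' @return smoothed `index_series` (name prefixed with "ma_"), or numeric
#'   vector when the input was one.
#' @export
moving_average <- function(series, window_s = 15) {
  stop_if_not(window_s >= 1, "window_s must be >= 1")
  x <- if (inherits(series, "index_series")) series$values else as.numeric(series)
  n <- length(x)
  if (n == 0) {
    out <- numeric(0)
  } else {
    xs <- ifelse(is.na(x), 0, x)
    cnt <- cumsum(!is.na(x))
    cs <- cumsum(xs)
    lag_i <- pmax(seq_len(n) - window_s, 0)
    cs_lag <- c(0, cs)[lag_i + 1]
    cnt_lag <- c(0, cnt)[lag_i + 1]
    m <- cnt - cnt_lag
    out <- ifelse(m > 0, (cs - cs_lag) / m, NA_real_)
  }
  if (inherits(series, "index_series")) {
    new_index_series(paste0("ma_", series$name), series$times_s, out)
  } else {
    out
  }
}

#' All standard EEG arousal index series for one recording
#'
#' Computes the four arousal-side indexes analyzed by the pipeline:
#' the Attention-Meditation surrogate difference, the 15 s moving average of
#' the high-beta/high-alpha ratio ("ma_hb_ha"), and the raw delta and theta
#' band powers. Gamma is excluded from analyses by default (muscle
#' artifacts) but remains accessible via [band_index()].
#'
#' @param signal EEG `raw_signal`.
#' @param ma_window_s smoothing window for the ratio index, s.
#' @return named list of `index_series`: `att_minus_med`, `ma_hb_ha`,
#'   `delta`, `theta`.
#' @export
eeg_index_series <- function(signal, ma_window_s = 15) {
  bp <- band_powers(signal)
  ratio <- moving_average(hbeta_halpha_ratio(bp), ma_window_s)
  ratio$name <- "ma_hb_ha"
  list(
    att_minus_med = att_minus_med(bp),
    ma_hb_ha = ratio,
    delta = band_index(bp, "delta"),
    theta = band_index(bp, "theta")
  )
}
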
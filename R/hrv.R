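#' Detect pulse peaks in a PPG signal
#'
#' Local maxima exceeding an adaptive threshold (rolling median plus
#' `k` times the rolling MAD, both over a `window_s` window) are accepted as
#' beats, subject to a 300 ms refractory period: a candidate closer than the
#' refractory period to the previously accepted beat is suppressed.
#'
#' @param signal a `raw_signal` (PPG) or numeric vector.
#' @param fs_hz sampling rate; taken from the signal when omitted.
#' @param k MAD multiplier of the adaptive threshold.
#' @param window_s rolling window length, s.
#' @param refractory_s minimum beat spacing, s.
#' @return numeric vector of strictly increasing beat times (s). A flat or
#'   sub-threshold signal yields an empty vector with a warning.
#' @export
detect_beats <- function(signal, fs_hz = NULL, k = 3, window_s = 2,
                         refractory_s = 0.3) {
  if (inherits(signal, "raw_signal")) {
    if (is.null(fs_hz)) fs_hz <- signal$fs_hz
    x <- signal$values
  } else {
    x <- as.numeric(signal)
    stop_if_not(!is.null(fs_hz), "fs_hz required for a bare numeric signal")
  }
  n <- length(x)
  stop_if_not(n >= 2 * fs_hz, "signal must be at least 2 s long")

  w <- floor(window_s * fs_hz)
  if (w %% 2 == 0) w <- w + 1
  w <- min(w, if (n %% 2 == 1) n else n - 1)
  med <- stats::runmed(x, w, endrule = "constant")
  mad_r <- 1.4826 * stats::runmed(abs(x - med), w, endrule = "constant")
  thr <- med + k * mad_r

  # strict local maxima: rising into the sample, falling out of it; the two
  # boundary samples count as maxima when they exceed their only neighbor
  dx <- diff(x)
  peaks <- which(dx[-(n - 1)] > 0 & dx[-1] < 0) + 1L
  if (x[1] > x[2]) peaks <- c(1L, peaks)
  if (x[n] > x[n - 1]) peaks <- c(peaks, n)
  peaks <- peaks[x[peaks] > thr[peaks]]

  if (!length(peaks)) {
    warning("no beats detected (flat or sub-threshold signal)")
    return(numeric(0))
  }
  # refractory suppression, greedy in time order
  keep <- peaks[1]
  last <- peaks[1]
  min_gap <- refractory_s * fs_hz
  for (p in peaks[-1]) {
    if (p - last >= min_gap) {
      keep <- c(keep, p)
      last <- p
    }
  }
  (keep - 1) / fs_hz
}

#' Inter-beat intervals from beat times
#'
#' Converts beat times to successive intervals (ms) and removes intervals
#' outside the physiologic range 300-2000 ms. Successive-difference pairs
#' adjacent to a removed interval are flagged invalid and excluded from the
#' HRV indexes; the number of removed intervals is reported via an attribute
#' and a message.
#'
#' @param beat_times_s strictly increasing beat times (s), or an `ibi_series`.
#' @return `ibi_series` with fields `beat_times_s`, `intervals_ms`,
#'   `valid` (logical per interval) and attribute `n_removed`.
#' @export
ibi_from_beats <- function(beat_times_s) {
  if (inherits(beat_times_s, "ibi_series")) beat_times_s <- beat_times_s$beat_times_s
  beat_times_s <- as.numeric(beat_times_s)
  stop_if_not(length(beat_times_s) >= 2,
              "insufficient data: at least 2 beats required")
  stop_if_not(all(diff(beat_times_s) > 0), "beat times must be strictly increasing")
  out <- new_ibi_series(beat_times_s)
  valid <- out$intervals_ms >= 300 & out$intervals_ms <= 2000
  n_removed <- sum(!valid)
  if (n_removed > 0) {
    message(sprintf("ibi_from_beats: removed %d implausible interval(s)", n_removed))
  }
  out$valid <- valid
  attr(out, "n_removed") <- n_removed
  out
}

# Successive differences of valid intervals whose second beat lies in
# [start_s, end_s). A difference is usable only if both intervals are valid.
window_diffs <- function(ibi, window = NULL) {
  iv <- ibi$intervals_ms
  valid <- if (is.null(ibi$valid)) rep(TRUE, length(iv)) else ibi$valid
  # interval j ends at beat j+1; window membership by the second beat
  second_beat <- ibi$beat_times_s[-1]
  in_win <- if (is.null(window)) rep(TRUE, length(iv)) else
    second_beat >= window[1] & second_beat < window[2]
  use <- valid & in_win
  if (sum(use) < 2) return(numeric(0))
  idx <- which(use)
  # only difference consecutive usable intervals that are adjacent in the
  # original sequence (no bridging across removed/out-of-window intervals)
  adj <- diff(idx) == 1
  iv[idx[-1]][adj] - iv[idx[-length(idx)]][adj]
}

#' pNN50: proportion of large successive inter-beat differences
#'
#' The proportion of successive NN-interval differences whose absolute value
#' strictly exceeds `threshold_ms` (default 50 ms), a parasympathetic-tone
#' index used here as the valence axis. Reported as a proportion in `[0, 1]`.
#'
#' @param ibi an `ibi_series`.
#' @param window optional `c(start_s, end_s)`; an interval belongs to the
#'   window if its second beat falls inside it.
#' @param threshold_ms difference threshold (ms), strict inequality.
#' @return proportion in `[0, 1]`, or `NA` when fewer than two intervals fall
#'   in the window.
#' @examples
#' ibi <- ibi_from_beats(c(0, .8, 1.66, 2.48, 3.36, 4.23))
#' pnn50(ibi)  # differences 60, -40, 60, -10 -> 0.5
#' @export
pnn50 <- function(ibi, window = NULL, threshold_ms = 50) {
  d <- window_diffs(ibi, window)
  if (!length(d)) return(NA_real_)
  mean(abs(d) > threshold_ms)
}

#' RMSSD: root mean square of successive inter-beat differences
#'
#' A vagal-tone / stress-relax index in ms, suited to ultra-short windows
#' (<= 60 s).
#'
#' @inheritParams pnn50
#' @return RMSSD in ms, or `NA` when fewer than two intervals fall in the
#'   window.
#' @export
rmssd <- function(ibi, window = NULL) {
  d <- window_diffs(ibi, window)
  if (!length(d)) return(NA_real_)
  sqrt(mean(d^2))
}

#' Both ultra-short-term HRV indexes over a window
#'
#' @inheritParams pnn50
#' @return list with `pnn50`, `rmssd`, `n_intervals` and `window`.
#' @export
hrv_indexes <- function(ibi, window = NULL) {
  d <- window_diffs(ibi, window)
  valid <- if (is.null(ibi$valid)) rep(TRUE, length(ibi$intervals_ms)) else ibi$valid
  second_beat <- ibi$beat_times_s[-1]
  in_win <- if (is.null(window)) rep(TRUE, length(valid)) else
    second_beat >= window[1] & second_beat < window[2]
  list(
    pnn50 = if (length(d)) mean(abs(d) > 50) else NA_real_,
    rmssd = if (length(d)) sqrt(mean(d^2)) else NA_real_,
    n_intervals = sum(valid & in_win),
    window = window
  )
}
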
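#' EEG frequency bands used by the arousal indexes
#'
#' The seven bands reported by consumer single-channel EEG headsets, with
#' their closed frequency ranges in Hz: delta 1-3, theta 4-7, low alpha 8-9,
#' high alpha 10-12, low beta 13-17, high beta 18-30, gamma 31-50. Gamma is
#' computed but excluded from the default analyses because of its
#' susceptibility to muscle artifacts; it stays available in outputs.
#'
#' @return A data.frame with columns `band`, `f_lo`, `f_hi` (Hz).
#' @examples
#' eeg_bands()
#' @export
eeg_bands <- function() {
  data.frame(
    band = c("delta", "theta", "low_alpha", "high_alpha",
             "low_beta", "high_beta", "gamma"),
    f_lo = c(1, 4, 8, 10, 13, 18, 31),
    f_hi = c(3, 7, 9, 12, 17, 30, 50),
    stringsAsFactors = FALSE
  )
}

band_names <- function() eeg_bands()$band

# Center frequency of a band, used by the sinusoid synthesis mode.
band_center <- function(band) {
  b <- eeg_bands()
  i <- match(band, b$band)
  stop_if_not(!anyNA(i), "unknown EEG band: %s",
              paste(band[is.na(i)], collapse = ", "))
  (b$f_lo[i] + b$f_hi[i]) / 2
}

check_band_vector <- function(x, what = "band amplitudes") {
  stop_if_not(is.numeric(x) && !is.null(names(x)),
              "%s must be a named numeric vector", what)
  missing <- setdiff(band_names(), names(x))
  stop_if_not(length(missing) == 0, "%s missing bands: %s", what,
              paste(missing, collapse = ", "))
  extra <- setdiff(names(x), band_names())
  stop_if_not(length(extra) == 0, "unknown band name: %s",
              paste(extra, collapse = ", "))
  stop_if_not(all(is.finite(x)) && all(x >= 0),
              "%s must be finite and non-negative", what)
  x[band_names()]
}
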
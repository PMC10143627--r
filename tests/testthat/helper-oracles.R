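# Independent loop-based reference implementations of the HRV indexes,
# kept deliberately naive so they cannot share a defect with the package.

ref_pnn50 <- function(intervals_ms, threshold_ms = 50) {
  n_big <- 0L
  n_all <- 0L
  for (k in 2:length(intervals_ms)) {
    d <- intervals_ms[k] - intervals_ms[k - 1]
    n_all <- n_all + 1L
    if (abs(d) > threshold_ms) n_big <- n_big + 1L
  }
  n_big / n_all
}

ref_rmssd <- function(intervals_ms) {
  acc <- 0
  n <- 0L
  for (k in 2:length(intervals_ms)) {
    acc <- acc + (intervals_ms[k] - intervals_ms[k - 1])^2
    n <- n + 1L
  }
  sqrt(acc / n)
}

# ibi_series from an explicit interval list (ms)
ibi_from_intervals <- function(intervals_ms) {
  aromamap::ibi_from_beats(cumsum(c(0, intervals_ms / 1000)))
}

# amplitude vector with a single active band
single_band_amp <- function(band, a = 1) {
  v <- stats::setNames(rep(0, 7), aromamap::eeg_bands()$band)
  v[band] <- a
  v
}

# fraction of total 1-50 Hz power falling in one band, per band_powers
band_fraction <- function(bp, band) {
  mean(bp$powers[, band] / rowSums(bp$powers))
}
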
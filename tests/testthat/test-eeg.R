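test_that("band powers are zero for a zero signal and reject low rates", {
  bp <- band_powers(rep(0, 512 * 3), fs_hz = 512)
  expect_identical(dim(bp$powers), c(3L, 7L))
  expect_true(all(bp$powers == 0))
  expect_equal(bp$epoch_times_s, 0:2)
  expect_error(band_powers(rep(0, 200), fs_hz = 60), "too low")
})

test_that("sinusoids land in their band in every epoch", {
  fs <- 512
  t <- (0:(fs * 20 - 1)) / fs
  bp_ha <- band_powers(sin(2 * pi * 10.5 * t), fs_hz = fs)
  frac_ha <- bp_ha$powers[, "high_alpha"] / rowSums(bp_ha$powers)
  expect_true(all(frac_ha >= 0.9))
  bp_d <- band_powers(sin(2 * pi * 2 * t), fs_hz = fs)
  frac_d <- bp_d$powers[, "delta"] / rowSums(bp_d$powers)
  expect_true(all(frac_d >= 0.9))
  expect_true(all(bp_d$powers[, c("theta", "low_alpha", "high_alpha",
                                  "low_beta", "high_beta", "gamma")] <
                    0.01 * bp_d$powers[, "delta"]))
})

test_that("band powers agree with an independent periodogram oracle", {
  # oracle: stats::spec.pgram on one Hann-tapered 1 s epoch, band-integrated
  fs <- 512
  set.seed(19)
  x <- rnorm(fs)
  bp <- band_powers(x, fs_hz = fs)
  spec <- stats::spec.pgram(stats::ts(x, frequency = fs), taper = 0.5,
                            detrend = FALSE, plot = FALSE,
                            pad = 0, fast = FALSE)
  # compare band *fractions* (scalings differ between estimators)
  b <- eeg_bands()
  oracle <- vapply(seq_len(nrow(b)), function(i) {
    sum(spec$spec[spec$freq >= b$f_lo[i] & spec$freq <= b$f_hi[i]])
  }, numeric(1))
  got <- bp$powers[1, ]
  expect_equal(unname(got / sum(got)), oracle / sum(oracle), tolerance = 0.02)
})

test_that("power scales with the square of the signal amplitude", {
  fs <- 512
  t <- (0:(fs * 5 - 1)) / fs
  x <- sin(2 * pi * 10.5 * t)
  p1 <- band_powers(x, fs_hz = fs)$powers
  p2 <- band_powers(2 * x, fs_hz = fs)$powers
  nz <- p1 > 0
  expect_equal(p2[nz] / p1[nz], rep(4, sum(nz)), tolerance = 1e-6)
})

test_that("surrogate attention/meditation are power shares on a 0-100 scale", {
  mk_bp <- function(p) {
    structure(list(epoch_times_s = 0, powers = matrix(p, nrow = 1,
               dimnames = list(NULL, eeg_bands()$band))),
              class = "band_power_series")
  }
  am <- surrogate_attention_meditation(mk_bp(c(0, 0, 0, 0, 1, 2, 0)))
  expect_identical(am$att$values, 100)
  expect_identical(am$med$values, 0)
  am_eq <- surrogate_attention_meditation(mk_bp(rep(1, 7)))
  expect_equal(am_eq$att$values, 200 / 7)
  expect_equal(am_eq$med$values, 200 / 7)
  # zero total power is undefined, not zero
  am0 <- surrogate_attention_meditation(mk_bp(rep(0, 7)))
  expect_true(is.na(am0$att$values))
  # shares of a partition: att + med <= 100, difference within [-100, 100]
  set.seed(23)
  for (rep in 1:50) {
    p <- runif(7, 0, 10)
    am_r <- surrogate_attention_meditation(mk_bp(p))
    expect_lte(am_r$att$values + am_r$med$values, 100 + 1e-9)
    d <- am_r$att$values - am_r$med$values
    expect_gte(d, -100); expect_lte(d, 100)
  }
})

test_that("high-beta/high-alpha ratio behaves and is scale invariant", {
  mk_bp <- function(hb, ha) {
    p <- matrix(c(1, 1, 1, ha, 1, hb, 1), nrow = 1,
                dimnames = list(NULL, eeg_bands()$band))
    structure(list(epoch_times_s = 0, powers = p), class = "band_power_series")
  }
  expect_equal(hbeta_halpha_ratio(mk_bp(3, 3))$values, 1, tolerance = 1e-9)
  expect_equal(hbeta_halpha_ratio(mk_bp(0, 2))$values, 0)
  expect_equal(hbeta_halpha_ratio(mk_bp(4, 2))$values, 2, tolerance = 1e-9)
  # overall rescaling of the signal leaves the ratio unchanged
  fs <- 512
  e <- generate_eeg(5, band_amplitudes = stats::setNames(rep(1, 7), eeg_bands()$band),
                    seed = 3)
  r1 <- hbeta_halpha_ratio(band_powers(e))$values
  e2 <- e; e2$values <- 3 * e$values
  r2 <- hbeta_halpha_ratio(band_powers(e2))$values
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("trailing moving average matches hand computation and its invariants", {
  expect_equal(moving_average(rep(3.5, 40), 15), rep(3.5, 40))
  x <- c(rep(0, 15), 15)
  expect_equal(moving_average(x, 15)[16], 1)
  # expanding prefix for the first window-1 samples
  expect_equal(moving_average(1:5, 3), c(1, 1.5, 2, 3, 4))
  # bounded by the input range; commutes with adding a constant
  set.seed(9)
  y <- rnorm(60)
  m <- moving_average(y, 15)
  expect_true(all(m >= min(y) - 1e-12 & m <= max(y) + 1e-12))
  expect_equal(moving_average(y + 2, 15), m + 2, tolerance = 1e-12)
  # NA samples are excluded from each mean
  z <- c(1, NA, 3)
  expect_equal(moving_average(z, 2), c(1, 1, 3))
  expect_length(moving_average(numeric(0), 15), 0)
  expect_error(moving_average(1:10, 0), ">= 1")
})

test_that("the standard index set is computed on a 1 Hz grid", {
  e <- generate_eeg(10, seed = 1)
  idx <- eeg_index_series(e)
  expect_named(idx, c("att_minus_med", "ma_hb_ha", "delta", "theta"))
  for (s in idx) {
    expect_s3_class(s, "index_series")
    expect_equal(s$times_s, 0:9)
  }
  expect_identical(idx$ma_hb_ha$name, "ma_hb_ha")
})
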
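test_that("zero-variability IBI series is exactly constant", {
  ibi <- generate_ibi_series(60, 800, 0, seed = 1)
  expect_true(all(ibi$intervals_ms == 800))
  expect_gte(max(ibi$beat_times_s), 60)
  expect_identical(pnn50(ibi), 0)
  expect_identical(rmssd(ibi), 0)
})

test_that("IBI generator rejects bad arguments", {
  expect_error(generate_ibi_series(0, 800, 10, seed = 1), "positive")
  expect_error(generate_ibi_series(60, 200, 10, seed = 1), "300")
  expect_error(generate_ibi_series(60, 800, -1, seed = 1), ">= 0")
})

test_that("IBI generator hits its closed-form RMSSD and pNN50 targets", {
  # E[RMSSD] -> sigma_d and E[pNN50] -> 2*Phi(-50/sigma_d) for Gaussian
  # successive differences; single long series as a quick check (the
  # 100-replicate version lives with the acceptance checks)
  ibi <- generate_ibi_series(300, 800, 30, seed = 7)
  expect_lt(abs(rmssd(ibi) - 30) / 30, 0.15)
  expect_lt(abs(pnn50(ibi) - 2 * pnorm(-50 / 30)), 0.05)
})

test_that("generators are deterministic given the seed", {
  a <- generate_ibi_series(120, 800, 30, seed = 5)
  b <- generate_ibi_series(120, 800, 30, seed = 5)
  expect_identical(a, b)
  expect_identical(generate_ppg(a, noise_sd = 0.1, seed = 3),
                   generate_ppg(b, noise_sd = 0.1, seed = 3))
  amp <- stats::setNames(rep(1, 7), eeg_bands()$band)
  expect_identical(generate_eeg(5, band_amplitudes = amp, seed = 9),
                   generate_eeg(5, band_amplitudes = amp, seed = 9))
  s1 <- generate_session(make_timeline(), effect_spec(), seed = 4)
  s2 <- generate_session(make_timeline(), effect_spec(), seed = 4)
  expect_identical(s1$eeg$values, s2$eeg$values)
  expect_identical(s1$ppg$values, s2$ppg$values)
})

test_that("PPG pulses peak at the beat times", {
  ibi <- ibi_from_beats(c(0.8, 1.6, 2.4))
  p <- generate_ppg(ibi, fs_hz = 500)
  t <- (seq_along(p$values) - 1) / 500
  for (bt in c(0.8, 1.6, 2.4)) {
    i <- which.min(abs(t - bt))
    win <- max(1, i - 50):min(length(p$values), i + 50)
    expect_lte(abs(t[win][which.max(p$values[win])] - bt), 1 / 500 + 1e-12)
  }
  expect_error(generate_ppg(structure(list(beat_times_s = numeric(0),
                                           intervals_ms = numeric(0)),
                                      class = "ibi_series")), "empty")
})

test_that("beat detection round-trips the generating IBI series", {
  for (mu in c(600, 800, 1000)) {
    ibi <- generate_ibi_series(120, mu, 25, seed = mu)
    bt <- detect_beats(generate_ppg(ibi))
    expect_length(bt, length(ibi$beat_times_s))
    expect_lt(max(abs(bt - ibi$beat_times_s)) * 1000, 20)
  }
})

test_that("EEG synthesis concentrates power in the generating band", {
  expect_identical(max(abs(generate_eeg(
    3, band_amplitudes = single_band_amp("delta", 0), seed = 1)$values)), 0)
  # filtered-noise mode: bands at least 3 Hz wide absorb the epoch-level
  # Hann leakage at their edges; the 2 Hz low-alpha band is validated via
  # the sinusoid mode below
  for (band in c("delta", "high_alpha", "gamma")) {
    e <- generate_eeg(20, band_amplitudes = single_band_amp(band), seed = 11)
    expect_gte(band_fraction(band_powers(e), band), 0.9)
  }
  e_la <- generate_eeg(20, band_amplitudes = single_band_amp("low_alpha"),
                       seed = 11, mode = "sinusoid")
  expect_gte(band_fraction(band_powers(e_la), "low_alpha"), 0.9)
  expect_error(generate_eeg(5, band_amplitudes = c(bogus = 1)), "band")
})

test_that("doubling one band amplitude quadruples its power, others unchanged", {
  amp1 <- stats::setNames(rep(1, 7), eeg_bands()$band)
  amp2 <- amp1
  amp2["high_beta"] <- 2
  p1 <- colMeans(band_powers(generate_eeg(30, band_amplitudes = amp1, seed = 13))$powers)
  p2 <- colMeans(band_powers(generate_eeg(30, band_amplitudes = amp2, seed = 13))$powers)
  expect_equal(unname(p2["high_beta"] / p1["high_beta"]), 4, tolerance = 0.05)
  # neighbors see only spectral leakage from the boosted band (< 2%)
  others <- setdiff(names(p1), "high_beta")
  expect_equal(p2[others], p1[others], tolerance = 0.02)
})

test_that("timeline construction enforces the protocol invariants", {
  tl <- make_timeline()
  expect_s3_class(tl, "session_timeline")
  expect_identical(nrow(tl$events), 7L)
  expect_identical(tl$events$name[7], "IVA")
  expect_identical(tl$events$duration_s, c(rep(60, 6), 30))
  expect_identical(tl$events$onset_s[1], 60)  # after the pre-rest minute
  expect_error(make_timeline(c("citrus", "citrus", "soap", "woody",
                               "fruity", "floral")), "permutation")
  bad <- tl
  bad$events$onset_s[2] <- bad$events$onset_s[1] + 10
  expect_error(generate_session(bad, effect_spec(), seed = 1), "overlap")
})

test_that("a raised stimulus sigma_d raises the measured pNN50 change", {
  eff <- effect_spec(baseline_sigma_d_ms = 25,
                     stimulus_sigma_d_ms = c(lavender = 45))
  s <- generate_session(make_timeline(), eff, seed = 21)
  si <- session_indexes(s)
  lav <- si$summaries[si$summaries$stimulus == "lavender" &
                        si$summaries$index == "pnn50" &
                        si$summaries$window == "all", ]
  expect_gt(lav$ex_mean, 0)
})

test_that("cohort generation reproduces the study composition and is seeded", {
  coh <- generate_cohort(signals = FALSE, seed = 3)
  expect_identical(nrow(coh$manifest), 62L)
  expect_identical(unname(lengths(group_participants(coh))), c(15L, 15L, 17L, 15L))
  coh2 <- generate_cohort(signals = FALSE, seed = 3)
  expect_identical(coh$manifest, coh2$manifest)
  expect_identical(coh$sessions[[1]]$timeline$events$name,
                   coh2$sessions[[1]]$timeline$events$name)
  one <- generate_cohort(data.frame(gender = "male", generation = "20s", n = 1),
                         signals = FALSE, seed = 1)
  expect_identical(nrow(one$manifest), 1L)
  # per-participant aroma order varies but the unpleasant odor is always last
  orders <- vapply(coh$sessions[1:8],
                   function(s) paste(s$timeline$events$name, collapse = ","),
                   character(1))
  expect_gt(length(unique(orders)), 1)
  expect_true(all(vapply(coh$sessions,
                         function(s) s$timeline$events$name[7] == "IVA",
                         logical(1))))
})
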
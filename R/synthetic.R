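#' Olfactory stimulus set
#'
#' The seven stimuli of the experimental protocol: six commercial aroma
#' stimuli (citrus, lavender, soap, woody, fruity, floral) presented for 60 s
#' each in randomized order, plus isovaleric acid (IVA) as an unpleasant odor,
#' always presented last and limited to 30 s.
#'
#' @return data.frame with columns `name`, `stim_type` ("aroma"/"unpleasant")
#'   and `duration_s`.
#' @export
stimulus_table <- function() {
  data.frame(
    name = c("citrus", "lavender", "soap", "woody", "fruity", "floral", "IVA"),
    stim_type = c(rep("aroma", 6), "unpleasant"),
    duration_s = c(rep(60, 6), 30),
    stringsAsFactors = FALSE
  )
}

#' Build a session timeline
#'
#' A session consists of a 60 s pre-stimulus resting minute, then each
#' stimulus exposure followed by a 60 s rest block (questionnaire time is
#' modeled as rest; it is not analyzed). The six aromas appear in the order
#' given; the unpleasant odor is always last.
#'
#' @param aroma_order character vector: a permutation of the six aroma names.
#' @param participant_id identifier string.
#' @param gender "male" or "female".
#' @param generation one of "20s", "30s", "40s", "50s".
#' @return An object of class `session_timeline`: list with `pre_rest`
#'   (onset, duration), `events` (data.frame name/stim_type/onset_s/
#'   duration_s), `total_s`, and participant metadata.
#' @examples
#' tl <- make_timeline()
#' tl$events
#' @export
make_timeline <- function(aroma_order = stimulus_table()$name[1:6],
                          participant_id = "P01",
                          gender = "male", generation = "20s") {
  st <- stimulus_table()
  aromas <- st$name[st$stim_type == "aroma"]
  stop_if_not(length(aroma_order) == 6 && setequal(aroma_order, aromas),
              "aroma_order must be a permutation of: %s",
              paste(aromas, collapse = ", "))
  stop_if_not(gender %in% c("male", "female"), "unknown gender: %s", gender)
  stop_if_not(generation %in% c("20s", "30s", "40s", "50s"),
              "unknown generation: %s", generation)
  order_full <- c(aroma_order, "IVA")
  onset <- 60
  ev <- do.call(rbind, lapply(order_full, function(nm) {
    d <- st$duration_s[st$name == nm]
    row <- data.frame(name = nm, stim_type = st$stim_type[st$name == nm],
                      onset_s = onset, duration_s = d,
                      stringsAsFactors = FALSE)
    onset <<- onset + d + 60  # 60 s rest after every exposure
    row
  }))
  structure(list(
    pre_rest = c(onset_s = 0, duration_s = 60),
    events = ev,
    total_s = onset,
    participant_id = participant_id,
    gender = gender,
    generation = generation
  ), class = "session_timeline")
}

validate_timeline <- function(tl) {
  stop_if_not(inherits(tl, "session_timeline"), "not a session_timeline")
  ev <- tl$events
  stop_if_not(nrow(ev) == 7, "timeline must contain exactly 7 stimulus events")
  stop_if_not(ev$stim_type[7] == "unpleasant",
              "the unpleasant odor must be the last stimulus")
  ok_dur <- ifelse(ev$stim_type == "aroma", 60, 30)
  stop_if_not(all(ev$duration_s == ok_dur),
              "exposure durations must be 60 s (aroma) / 30 s (unpleasant)")
  ends <- ev$onset_s + ev$duration_s
  stop_if_not(all(ev$onset_s >= 0) && all(ev$onset_s[-1] >= ends[-7]),
              "stimulus events overlap")
  invisible(tl)
}

#' Stimulus effect specification for the synthetic generator
#'
#' Encodes the stimulus-dependent shifts the analysis must recover: a
#' per-stimulus multiplier on each EEG band amplitude and a per-stimulus
#' standard deviation of successive inter-beat-interval differences
#' (`sigma_d`, ms), plus baseline values used during rest.
#'
#' Defaults are illustrative plausible values (the magnitudes of real stimulus
#' effects in physical units are unknown): all multipliers 1 and sigma_d equal
#' to baseline, i.e. a null specification.
#'
#' @param baseline_mean_ibi_ms mean inter-beat interval during rest (ms).
#' @param baseline_sigma_d_ms sd of successive IBI differences during rest.
#' @param baseline_band_amp named amplitude per EEG band during rest.
#' @param stimulus_band_mult named list: stimulus -> named multiplier vector
#'   (one per band). Stimuli not listed use multipliers of 1.
#' @param stimulus_sigma_d_ms named numeric: stimulus -> sigma_d (ms). Stimuli
#'   not listed use the baseline value.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(baseline_mean_ibi_ms = 800,
                        baseline_sigma_d_ms = 25,
                        baseline_band_amp = stats::setNames(rep(1, 7), band_names()),
                        stimulus_band_mult = list(),
                        stimulus_sigma_d_ms = numeric(0)) {
  stop_if_not(baseline_mean_ibi_ms >= 300 && baseline_mean_ibi_ms <= 2000,
              "baseline mean IBI must lie in [300, 2000] ms")
  stop_if_not(baseline_sigma_d_ms >= 0, "sigma_d must be >= 0")
  baseline_band_amp <- check_band_vector(baseline_band_amp)
  stim_names <- stimulus_table()$name
  for (nm in names(stimulus_band_mult)) {
    stop_if_not(nm %in% stim_names, "unknown stimulus in band multipliers: %s", nm)
    m <- check_band_vector(stimulus_band_mult[[nm]], "band multipliers")
    stop_if_not(all(m > 0), "band multipliers must be > 0")
    stimulus_band_mult[[nm]] <- m
  }
  for (nm in names(stimulus_sigma_d_ms)) {
    stop_if_not(nm %in% stim_names, "unknown stimulus in sigma_d: %s", nm)
    stop_if_not(stimulus_sigma_d_ms[[nm]] >= 0, "sigma_d must be >= 0")
  }
  structure(list(
    baseline_mean_ibi_ms = baseline_mean_ibi_ms,
    baseline_sigma_d_ms = baseline_sigma_d_ms,
    baseline_band_amp = baseline_band_amp,
    stimulus_band_mult = stimulus_band_mult,
    stimulus_sigma_d_ms = stimulus_sigma_d_ms
  ), class = "effect_spec")
}

spec_sigma_d <- function(spec, stimulus) {
  if (stimulus %in% names(spec$stimulus_sigma_d_ms)) {
    spec$stimulus_sigma_d_ms[[stimulus]]
  } else {
    spec$baseline_sigma_d_ms
  }
}

spec_band_amp <- function(spec, stimulus = NULL) {
  amp <- spec$baseline_band_amp
  if (!is.null(stimulus) && stimulus %in% names(spec$stimulus_band_mult)) {
    amp <- amp * spec$stimulus_band_mult[[stimulus]]
  }
  amp
}

new_raw_signal <- function(values, fs_hz, channel) {
  structure(list(values = as.numeric(values), fs_hz = fs_hz, channel = channel),
            class = "raw_signal")
}

new_ibi_series <- function(beat_times_s, intervals_ms = NULL) {
  beat_times_s <- as.numeric(beat_times_s)
  if (is.null(intervals_ms)) intervals_ms <- diff(beat_times_s) * 1000
  structure(list(
    beat_times_s = beat_times_s,
    intervals_ms = intervals_ms
  ), class = "ibi_series")
}

#' Simulate an inter-beat-interval series with controlled variability
#'
#' Intervals follow a mean-reverting (AR(1)) Gaussian process around
#' `mean_ibi_ms`, parameterized so that successive interval differences are
#' zero-mean Gaussian with standard deviation `sigma_d_ms` in stationarity.
#' This gives closed-form targets for the two ultra-short-term HRV indexes:
#' the expected RMSSD tends to `sigma_d_ms` and the expected pNN50 to
#' `2 * pnorm(-50 / sigma_d_ms)`. Intervals are clamped to the physiologic
#' range 300-2000 ms.
#'
#' @param duration_s length of the series in seconds; beats cover
#'   `[0, duration_s]`.
#' @param mean_ibi_ms mean interval, ms, in `[300, 2000]`.
#' @param sigma_d_ms target sd of successive interval differences, ms.
#' @param seed integer seed; output is deterministic given the seed.
#' @param phi AR(1) mean-reversion coefficient in `[0, 1)`.
#' @return Object of class `ibi_series` with `beat_times_s` and
#'   `intervals_ms`.
#' @examples
#' ibi <- generate_ibi_series(60, 800, 30, seed = 1)
#' rmssd(ibi)
#' @export
generate_ibi_series <- function(duration_s, mean_ibi_ms, sigma_d_ms, seed,
                                phi = 0.9) {
  stop_if_not(duration_s > 0, "duration_s must be positive")
  stop_if_not(mean_ibi_ms >= 300 && mean_ibi_ms <= 2000,
              "mean_ibi_ms must lie in [300, 2000]")
  stop_if_not(sigma_d_ms >= 0, "sigma_d_ms must be >= 0")
  stop_if_not(phi >= 0 && phi < 1, "phi must lie in [0, 1)")
  with_seed(seed, {
    # innovation sd chosen so that Var(x_t - x_{t-1}) = sigma_d^2
    sigma_e <- sigma_d_ms * sqrt((1 + phi) / 2)
    sigma_x <- if (phi < 1) sigma_e / sqrt(1 - phi^2) else 0
    n_max <- ceiling(duration_s * 1000 / 300) + 2
    x <- numeric(n_max)
    x[1] <- mean_ibi_ms + stats::rnorm(1, 0, sigma_x)
    eps <- stats::rnorm(n_max, 0, sigma_e)
    for (k in 2:n_max) {
      x[k] <- mean_ibi_ms + phi * (x[k - 1] - mean_ibi_ms) + eps[k]
    }
    x <- pmin(pmax(x, 300), 2000)
    beats <- c(0, cumsum(x / 1000))
    # trim to the first beat at or past duration_s so beats cover [0, duration]
    last <- which(beats >= duration_s)[1]
    if (!is.na(last)) {
      beats <- beats[seq_len(last)]
      x <- x[seq_len(last - 1)]
    }
    new_ibi_series(beats, intervals_ms = x)
  })
}

#' Synthesize a PPG signal from beat times
#'
#' Places one smooth unimodal (Gaussian) pulse at each beat time, plus
#' optional white noise. The pulse peak is unambiguous, so beat detection can
#' be validated by round-trip against the generating series.
#'
#' @param ibi an `ibi_series`.
#' @param fs_hz sampling rate, Hz (pulse sensor default 500).
#' @param pulse_width_s pulse width; the Gaussian sd is `pulse_width_s / 2`.
#' @param noise_sd white noise sd added to the signal.
#' @param seed seed for the noise; deterministic given seed.
#' @return `raw_signal` with channel "PPG".
#' @export
generate_ppg <- function(ibi, fs_hz = 500, pulse_width_s = 0.12,
                         noise_sd = 0, seed = 0) {
  stop_if_not(inherits(ibi, "ibi_series"), "ibi must be an ibi_series")
  stop_if_not(length(ibi$beat_times_s) >= 1, "empty IBI series")
  stop_if_not(fs_hz > 2 / pulse_width_s,
              "fs_hz too low to resolve the pulse width")
  dur <- max(ibi$beat_times_s)
  n <- floor(dur * fs_hz) + 1
  t <- (seq_len(n) - 1) / fs_hz
  sd_p <- pulse_width_s / 2
  sig <- numeric(n)
  for (bt in ibi$beat_times_s) {
    lo <- max(1L, floor((bt - 4 * sd_p) * fs_hz) + 1L)
    hi <- min(n, ceiling((bt + 4 * sd_p) * fs_hz) + 1L)
    idx <- lo:hi
    sig[idx] <- sig[idx] + exp(-0.5 * ((t[idx] - bt) / sd_p)^2)
  }
  if (noise_sd > 0) {
    sig <- sig + with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  new_raw_signal(sig, fs_hz, "PPG")
}

# Band-limited white noise via FFT masking, unit RMS before scaling.
band_noise <- function(n, fs_hz, f_lo, f_hi) {
  z <- stats::rnorm(n)
  Z <- stats::fft(z)
  f <- (seq_len(n) - 1) * fs_hz / n
  f_fold <- pmin(f, fs_hz - f)
  mask <- f_fold >= f_lo & f_fold <= f_hi
  Z[!mask] <- 0
  y <- Re(stats::fft(Z, inverse = TRUE)) / n
  r <- sqrt(mean(y^2))
  if (r > 0) y / r else y
}

#' Synthesize an EEG signal with a prescribed band-power structure
#'
#' The signal is a sum over the seven standard bands of band-limited noise
#' (or a pure sinusoid at the band center, for exact spectral tests), each
#' scaled by its amplitude, plus optional white noise. Band power estimated
#' downstream scales with amplitude squared.
#'
#' @param duration_s signal length in seconds.
#' @param fs_hz sampling rate, Hz (EEG sensor default 512).
#' @param band_amplitudes named non-negative amplitude per band (see
#'   [eeg_bands()]).
#' @param noise_sd white (broadband) noise sd.
#' @param seed seed; deterministic given seed.
#' @param mode "noise" for band-limited noise, "sinusoid" for band-center
#'   sinusoids.
#' @return `raw_signal` with channel "EEG".
#' @export
generate_eeg <- function(duration_s, fs_hz = 512,
                         band_amplitudes = stats::setNames(rep(1, 7), band_names()),
                         noise_sd = 0, seed = 0, mode = c("noise", "sinusoid")) {
  mode <- match.arg(mode)
  stop_if_not(duration_s > 0, "duration_s must be positive")
  band_amplitudes <- check_band_vector(band_amplitudes)
  n <- round(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  b <- eeg_bands()
  with_seed(seed, {
    sig <- numeric(n)
    for (i in seq_len(nrow(b))) {
      a <- band_amplitudes[[b$band[i]]]
      if (a == 0) next
      comp <- if (mode == "sinusoid") {
        sqrt(2) * sin(2 * pi * band_center(b$band[i]) * t)  # unit RMS
      } else {
        band_noise(n, fs_hz, b$f_lo[i], b$f_hi[i])
      }
      sig <- sig + a * comp
    }
    if (noise_sd > 0) sig <- sig + stats::rnorm(n, 0, noise_sd)
    new_raw_signal(sig, fs_hz, "EEG")
  })
}

#' Generate one complete experimental session
#'
#' Produces contiguous EEG and PPG recordings covering the whole timeline.
#' Within each stimulus exposure window the generators use that stimulus's
#' effect parameters; rest windows (including the pre-stimulus baseline
#' minute) use the baseline parameters.
#'
#' @param timeline a `session_timeline`.
#' @param effects an `effect_spec`.
#' @param seed root seed, split internally per channel and condition.
#' @param eeg_fs,ppg_fs sampling rates.
#' @param eeg_noise_sd,ppg_noise_sd additive white noise levels.
#' @return list with elements `eeg` (`raw_signal`), `ppg` (`raw_signal`),
#'   `ibi` (the generating `ibi_series`, for reference) and `timeline`.
#' @export
generate_session <- function(timeline, effects = effect_spec(), seed = 0,
                             eeg_fs = 512, ppg_fs = 500,
                             eeg_noise_sd = 0, ppg_noise_sd = 0) {
  validate_timeline(timeline)
  stop_if_not(inherits(effects, "effect_spec"), "effects must be an effect_spec")
  ev <- timeline$events
  total <- timeline$total_s

  # Condition schedule: rest everywhere except exposure windows.
  cond_at <- function(t_s) {
    hit <- which(t_s >= ev$onset_s & t_s < ev$onset_s + ev$duration_s)
    if (length(hit)) ev$name[hit[1]] else NA_character_
  }

  # --- PPG: sequential AR(1) interval walk whose sigma_d switches with the
  # condition active at each beat time.
  phi <- 0.9
  mu <- effects$baseline_mean_ibi_ms
  beats <- with_seed(child_seed(seed, 1), {
    bt <- 0
    x_prev <- mu
    out <- numeric(0)
    repeat {
      out <- c(out, bt)
      if (bt >= total) break
      stim <- cond_at(bt)
      sd_d <- if (is.na(stim)) effects$baseline_sigma_d_ms else
        spec_sigma_d(effects, stim)
      sigma_e <- sd_d * sqrt((1 + phi) / 2)
      x <- mu + phi * (x_prev - mu) + stats::rnorm(1, 0, sigma_e)
      x <- min(max(x, 300), 2000)
      x_prev <- x
      bt <- bt + x / 1000
    }
    out
  })
  ibi <- new_ibi_series(beats)
  ppg <- generate_ppg(ibi, fs_hz = ppg_fs, noise_sd = ppg_noise_sd,
                      seed = child_seed(seed, 2))

  # --- EEG: piecewise synthesis, one segment per condition block.
  breaks <- sort(unique(c(0, ev$onset_s, ev$onset_s + ev$duration_s, total)))
  segs <- vector("list", length(breaks) - 1)
  for (i in seq_along(segs)) {
    lo <- breaks[i]; hi <- breaks[i + 1]
    stim <- cond_at(lo)
    amp <- spec_band_amp(effects, stim)
    segs[[i]] <- generate_eeg(hi - lo, fs_hz = eeg_fs, band_amplitudes = amp,
                              noise_sd = eeg_noise_sd,
                              seed = child_seed(seed, 3, i))$values
  }
  eeg <- new_raw_signal(unlist(segs), eeg_fs, "EEG")

  list(eeg = eeg, ppg = ppg, ibi = ibi, timeline = timeline)
}

#' Default cohort composition
#'
#' Participant counts by gender and decade emulating the study cohort:
#' 9/6 male 20s/30s, 10/7 female 20s/30s, 3/12 male 40s/50s, 9/6 female
#' 40s/50s — 62 in total, grouping into four gender-by-generation-band groups
#' of 15, 17, 15 and 15.
#'
#' @return data.frame with columns `gender`, `generation`, `n`.
#' @export
default_composition <- function() {
  data.frame(
    gender = c("male", "female", "male", "female", "male", "female", "male", "female"),
    generation = c("20s", "20s", "30s", "30s", "40s", "40s", "50s", "50s"),
    n = c(9, 10, 6, 7, 3, 9, 12, 6),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic cohort of sessions
#'
#' Each participant gets a random order of the six aromas (the unpleasant
#' odor is always last) and a session generated from the group's effect
#' specification with optional participant-level jitter on the HRV
#' variability parameter.
#'
#' @param composition data.frame gender/generation/n (default:
#'   [default_composition()]).
#' @param group_effects either a single `effect_spec` applied to everyone, or
#'   a named list keyed by group ("male_20s30s", "male_40s50s",
#'   "female_20s30s", "female_40s50s").
#' @param seed root seed; the cohort is reproducible given the seed.
#' @param participant_jitter_sd sd (ms) of participant-level jitter added to
#'   all sigma_d parameters.
#' @param signals if FALSE, only timelines and the manifest are generated
#'   (cheap; useful for design checks).
#' @param ... passed on to [generate_session()].
#' @return Object of class `aroma_cohort`: list with `manifest` (data.frame
#'   participant_id/gender/generation/group) and `sessions` (list; NULL
#'   elements when `signals = FALSE` except the `timeline`).
#' @export
generate_cohort <- function(composition = default_composition(),
                            group_effects = effect_spec(), seed = 0,
                            participant_jitter_sd = 0, signals = TRUE, ...) {
  stop_if_not(is.data.frame(composition) &&
                all(c("gender", "generation", "n") %in% names(composition)),
              "composition must have columns gender, generation, n")
  aromas <- stimulus_table()$name[1:6]
  rows <- composition[rep(seq_len(nrow(composition)), composition$n), , drop = FALSE]
  n_total <- nrow(rows)
  manifest <- data.frame(
    participant_id = sprintf("P%03d", seq_len(max(n_total, 1))[seq_len(n_total)]),
    gender = rows$gender,
    generation = rows$generation,
    stringsAsFactors = FALSE
  )
  manifest$group <- group_key(manifest$gender, manifest$generation)
  sessions <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    ord <- with_seed(child_seed(seed, 100, i), sample(aromas))
    tl <- make_timeline(ord, participant_id = manifest$participant_id[i],
                        gender = manifest$gender[i],
                        generation = manifest$generation[i])
    eff <- if (inherits(group_effects, "effect_spec")) group_effects
           else group_effects[[manifest$group[i]]]
    stop_if_not(inherits(eff, "effect_spec"),
                "no effect_spec for group %s", manifest$group[i])
    if (participant_jitter_sd > 0) {
      j <- with_seed(child_seed(seed, 200, i),
                     stats::rnorm(1, 0, participant_jitter_sd))
      eff$baseline_sigma_d_ms <- max(0, eff$baseline_sigma_d_ms + j)
      if (length(eff$stimulus_sigma_d_ms)) {
        eff$stimulus_sigma_d_ms <- pmax(0, eff$stimulus_sigma_d_ms + j)
      }
    }
    sessions[[i]] <- if (signals) {
      generate_session(tl, eff, seed = child_seed(seed, 300, i), ...)
    } else {
      list(timeline = tl)
    }
  }
  structure(list(manifest = manifest, sessions = sessions, seed = seed),
            class = "aroma_cohort")
}
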
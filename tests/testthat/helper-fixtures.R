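# Shared small fixtures, generated once per test run and memoized.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# Three participants in one group under a null effect specification.
fixture_cohort <- function() {
  memo("cohort_null", generate_cohort(
    data.frame(gender = "male", generation = "20s", n = 3),
    effect_spec(), seed = 42
  ))
}

fixture_analysis <- function() {
  memo("analysis_null", aroma_analysis(fixture_cohort()))
}

# Alpha-dominant EEG with raised stimulus-time HRV variability: raw pNN50
# above its resting mean and negative attention-meditation, i.e. a group
# engineered to land in the low-arousal / high-valence quadrant.
lahv_effects <- function() {
  amp <- stats::setNames(c(1, 1, 2, 2, 0.5, 0.5, 0.5), eeg_bands()$band)
  sd_stim <- stats::setNames(rep(45, 7), stimulus_table()$name)
  effect_spec(baseline_sigma_d_ms = 25,
              baseline_band_amp = amp,
              stimulus_sigma_d_ms = sd_stim)
}

map_axes_for_test <- function(an, g, arousal_index = "att_minus_med") {
  aromamap:::map_axes(an, g, arousal_index)
}

fixture_lahv_analysis <- function() {
  memo("analysis_lahv", aroma_analysis(generate_cohort(
    data.frame(gender = "female", generation = "20s", n = 3),
    lahv_effects(), seed = 7
  )))
}
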
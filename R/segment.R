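#' Gender-by-generation group key
#'
#' Participants are grouped into four groups by gender and generation band:
#' 20s/30s form the "20s30s" band (ages 20-39) and 40s/50s the "40s50s" band
#' (ages 40-59).
#'
#' @param gender "male"/"female" (vectorized).
#' @param generation "20s","30s","40s","50s" (vectorized).
#' @return character vector, e.g. "male_20s30s".
#' @export
group_key <- function(gender, generation) {
  stop_if_not(all(gender %in% c("male", "female")),
              "unknown gender label")
  stop_if_not(all(generation %in% c("20s", "30s", "40s", "50s")),
              "unknown generation label: %s",
              paste(setdiff(generation, c("20s", "30s", "40s", "50s")), collapse = ", "))
  band <- ifelse(generation %in% c("20s", "30s"), "20s30s", "40s50s")
  paste(gender, band, sep = "_")
}

#' Partition a cohort manifest into the four analysis groups
#'
#' @param manifest data.frame with columns `participant_id`, `gender`,
#'   `generation` (an `aroma_cohort` is also accepted).
#' @return named list of four character vectors of participant ids, keyed by
#'   group; every participant appears in exactly one group.
#' @export
group_participants <- function(manifest) {
  if (inherits(manifest, "aroma_cohort")) manifest <- manifest$manifest
  stop_if_not(all(c("participant_id", "gender", "generation") %in% names(manifest)),
              "manifest needs participant_id, gender, generation columns")
  keys <- c("male_20s30s", "male_40s50s", "female_20s30s", "female_40s50s")
  g <- if (nrow(manifest)) group_key(manifest$gender, manifest$generation) else character(0)
  out <- lapply(keys, function(k) manifest$participant_id[g == k])
  names(out) <- keys
  out
}

#' Slice an index series by experimental condition
#'
#' Returns the baseline slice (the pre-stimulus resting minute) and, for each
#' stimulus, slices for the whole exposure and its first and latter halves.
#' Halves split at `duration / 2` (30 s for aromas, 15 s for the unpleasant
#' odor) with half-open windows `[onset, mid)` / `[mid, end)` on the 1 Hz
#' epoch grid, so no sample is double-counted.
#'
#' @param timeline a `session_timeline`.
#' @param series an `index_series` on the 1 Hz epoch grid.
#' @return list with `baseline` (`index_series`) and `stimuli`: per stimulus
#'   a list of `index_series` slices `all`, `first_half`, `latter_half`, plus
#'   `window` start/end times.
#' @export
segment_session <- function(timeline, series) {
  validate_timeline(timeline)
  stop_if_not(inherits(series, "index_series"), "series must be an index_series")
  t <- series$times_s
  ends <- timeline$events$onset_s + timeline$events$duration_s
  last_t <- max(t) + 1  # epochs are [t, t+1)
  for (i in seq_len(nrow(timeline$events))) {
    stop_if_not(ends[i] <= last_t,
                "stimulus '%s' extends past the end of the recording",
                timeline$events$name[i])
  }
  slice <- function(lo, hi) {
    sel <- t >= lo & t < hi
    new_index_series(series$name, t[sel], series$values[sel])
  }
  b0 <- timeline$pre_rest[["onset_s"]]
  baseline <- slice(b0, b0 + timeline$pre_rest[["duration_s"]])
  stimuli <- lapply(seq_len(nrow(timeline$events)), function(i) {
    on <- timeline$events$onset_s[i]
    d <- timeline$events$duration_s[i]
    list(
      all = slice(on, on + d),
      first_half = slice(on, on + d / 2),
      latter_half = slice(on + d / 2, on + d),
      window = c(start_s = on, end_s = on + d)
    )
  })
  names(stimuli) <- timeline$events$name
  list(baseline = baseline, stimuli = stimuli)
}

#' Baseline average of an index (Bavg)
#'
#' Arithmetic mean of the defined samples of the baseline resting slice. This
#' is the neutral-state reference subtracted from every exposure sample.
#'
#' @param baseline_slice `index_series` (or numeric vector) over the baseline
#'   window.
#' @return list with `index_name`, `b_avg` and `n` (number of defined
#'   samples). Errors when every sample is undefined (such a participant is
#'   excluded from analysis).
#' @export
baseline_average <- function(baseline_slice) {
  x <- if (inherits(baseline_slice, "index_series")) baseline_slice$values else
    as.numeric(baseline_slice)
  nm <- if (inherits(baseline_slice, "index_series")) baseline_slice$name else NA_character_
  n <- sum(!is.na(x))
  stop_if_not(n >= 1, "baseline has no defined samples; participant excluded")
  list(index_name = nm, b_avg = mean(x, na.rm = TRUE), n = n)
}

#' Baseline-change normalization (EX = Exi - Bavg)
#'
#' Subtracts the participant's baseline average from every sample of an
#' exposure slice, yielding the change of the index from the neutral resting
#' state. Undefined samples stay undefined.
#'
#' @param slice `index_series` of exposure samples (Exi).
#' @param b baseline statistics from [baseline_average()].
#' @return `index_series` of changes.
#' @export
normalize_index <- function(slice, b) {
  stop_if_not(inherits(slice, "index_series"), "slice must be an index_series")
  if (!is.na(b$index_name)) {
    stop_if_not(identical(slice$name, b$index_name),
                "index name mismatch: slice '%s' vs baseline '%s'",
                slice$name, b$index_name)
  }
  new_index_series(slice$name, slice$times_s, slice$values - b$b_avg)
}

#' Mean change over an exposure window
#'
#' Mean of the defined normalized samples. If more than `max_undefined_frac`
#' of the window is undefined the summary itself is undefined and excluded
#' downstream (with a message).
#'
#' @param ex `index_series` of normalized changes over the window.
#' @param max_undefined_frac tolerated fraction of undefined samples.
#' @return mean change, or `NA` with a message.
#' @export
summarize_exposure <- function(ex, max_undefined_frac = 0.5) {
  stop_if_not(inherits(ex, "index_series"), "ex must be an index_series")
  x <- ex$values
  if (!length(x)) return(NA_real_)
  frac_na <- mean(is.na(x))
  if (frac_na > max_undefined_frac) {
    message(sprintf("summarize_exposure: %.0f%% of window undefined; summary dropped",
                    100 * frac_na))
    return(NA_real_)
  }
  mean(x, na.rm = TRUE)
}
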
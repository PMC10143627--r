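#' Index summaries for one recorded session
#'
#' Runs the full extraction chain on one session: EEG band powers and arousal
#' index series, PPG beat detection and interval cleaning, then per-condition
#' segmentation, baseline averaging and baseline-change normalization.
#'
#' For the 1 Hz EEG indexes the raw window mean and the normalized change
#' (raw mean minus baseline average) are reported per stimulus and exposure
#' window. The two HRV indexes are computed directly per analysis window from
#' the interval series (not as a 1 Hz stream) and normalized against their
#' value over the baseline resting minute.
#'
#' @param session list with `eeg`, `ppg`, `timeline` (as from
#'   [generate_session()] or [read_session_csv()]).
#' @param ma_window_s moving-average window for the ratio index, s.
#' @return list with `summaries` (data.frame: participant_id, group,
#'   stimulus, window, index, raw_mean, ex_mean) and `baselines` (data.frame:
#'   participant_id, group, index, b_avg, n).
#' @export
session_indexes <- function(session, ma_window_s = 15) {
  tl <- validate_timeline(session$timeline)
  pid <- tl$participant_id
  grp <- group_key(tl$gender, tl$generation)

  # EEG chain
  eeg_idx <- eeg_index_series(session$eeg, ma_window_s = ma_window_s)

  # PPG chain
  beats <- detect_beats(session$ppg)
  ibi <- ibi_from_beats(beats)

  windows <- c("all", "first_half", "latter_half")
  sm <- list()
  bl <- list()

  for (nm in names(eeg_idx)) {
    seg <- segment_session(tl, eeg_idx[[nm]])
    b <- baseline_average(seg$baseline)
    bl[[length(bl) + 1]] <- data.frame(
      participant_id = pid, group = grp, index = nm, b_avg = b$b_avg, n = b$n,
      stringsAsFactors = FALSE
    )
    for (s in names(seg$stimuli)) {
      for (w in windows) {
        raw <- summarize_exposure(seg$stimuli[[s]][[w]])
        ex <- summarize_exposure(normalize_index(seg$stimuli[[s]][[w]], b))
        sm[[length(sm) + 1]] <- data.frame(
          participant_id = pid, group = grp, stimulus = s, window = w,
          index = nm, raw_mean = raw, ex_mean = ex, stringsAsFactors = FALSE
        )
      }
    }
  }

  # HRV chain: per-window scalars, baseline = pre-rest minute
  b0 <- tl$pre_rest[["onset_s"]]
  base_win <- c(b0, b0 + tl$pre_rest[["duration_s"]])
  base_hrv <- hrv_indexes(ibi, base_win)
  for (nm in c("pnn50", "rmssd")) {
    stop_if_not(is.finite(base_hrv[[nm]]),
                "baseline %s undefined; participant excluded", nm)
    bl[[length(bl) + 1]] <- data.frame(
      participant_id = pid, group = grp, index = nm, b_avg = base_hrv[[nm]],
      n = base_hrv$n_intervals, stringsAsFactors = FALSE
    )
  }
  ev <- tl$events
  for (i in seq_len(nrow(ev))) {
    on <- ev$onset_s[i]; d <- ev$duration_s[i]
    wins <- list(all = c(on, on + d),
                 first_half = c(on, on + d / 2),
                 latter_half = c(on + d / 2, on + d))
    for (w in windows) {
      h <- hrv_indexes(ibi, wins[[w]])
      for (nm in c("pnn50", "rmssd")) {
        sm[[length(sm) + 1]] <- data.frame(
          participant_id = pid, group = grp, stimulus = ev$name[i], window = w,
          index = nm, raw_mean = h[[nm]],
          ex_mean = h[[nm]] - base_hrv[[nm]], stringsAsFactors = FALSE
        )
      }
    }
  }

  list(summaries = do.call(rbind, sm), baselines = do.call(rbind, bl))
}

#' Analyze a cohort of sessions
#'
#' The package's central analysis. For every participant the six biological
#' indexes (att_minus_med, ma_hb_ha, delta, theta, pnn50, rmssd) are
#' extracted, segmented by stimulus and exposure window, and normalized as
#' changes from the pre-stimulus resting baseline. Per gender-by-generation
#' group, index and exposure half, the normalized changes enter a
#' within-subject repeated-measures ANOVA over the seven stimuli with
#' unadjusted post hoc paired comparisons.
#'
#' @param cohort an `aroma_cohort` (from [generate_cohort()] or assembled
#'   from [read_session_csv()] sessions).
#' @param ma_window_s moving-average window, s.
#' @param stat_windows exposure windows entering the ANOVA (default the two
#'   halves, as in the study design).
#' @param min_group_n smallest group size for which tests are attempted.
#' @return Object of class `aroma_analysis`: list with `summaries`,
#'   `baselines`, `anova` (one row per group x index x window), `pairwise`
#'   (21 rows per test), `groups`, `manifest`.
#' @examples
#' \donttest{
#' coh <- generate_cohort(data.frame(gender = "male", generation = "20s", n = 3),
#'                        seed = 1)
#' an <- aroma_analysis(coh)
#' summary(an)
#' }
#' @export
aroma_analysis <- function(cohort, ma_window_s = 15,
                           stat_windows = c("first_half", "latter_half"),
                           min_group_n = 3) {
  stop_if_not(inherits(cohort, "aroma_cohort"), "cohort must be an aroma_cohort")
  stop_if_not(length(cohort$sessions) > 0 && !is.null(cohort$sessions[[1]]$eeg),
              "cohort carries no signals; regenerate with signals = TRUE")
  per <- lapply(cohort$sessions, session_indexes, ma_window_s = ma_window_s)
  summaries <- do.call(rbind, lapply(per, `[[`, "summaries"))
  baselines <- do.call(rbind, lapply(per, `[[`, "baselines"))
  groups <- group_participants(cohort$manifest)
  indexes <- c("att_minus_med", "ma_hb_ha", "delta", "theta", "pnn50", "rmssd")
  stims <- stimulus_table()$name

  an_rows <- list()
  pw_rows <- list()
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) < min_group_n) next
    for (idx in indexes) {
      for (w in stat_windows) {
        sub <- summaries[summaries$participant_id %in% ids &
                           summaries$index == idx & summaries$window == w, ]
        m <- matrix(NA_real_, nrow = length(ids), ncol = length(stims),
                    dimnames = list(ids, stims))
        for (r in seq_len(nrow(sub))) {
          m[sub$participant_id[r], sub$stimulus[r]] <- sub$ex_mean[r]
        }
        n_complete <- sum(stats::complete.cases(m))
        if (n_complete < min_group_n) next
        a <- rm_anova(m)
        an_rows[[length(an_rows) + 1]] <- data.frame(
          group = g, index = idx, window = w, n = a$n,
          F = a$F, df_num = a$df_num, df_den = a$df_den, p = a$p,
          gg_epsilon = a$gg_epsilon, p_gg = a$p_gg, stringsAsFactors = FALSE
        )
        pw <- posthoc_pairwise(m)
        pw$group <- g; pw$index <- idx; pw$window <- w
        pw_rows[[length(pw_rows) + 1]] <- pw
      }
    }
  }

  structure(list(
    summaries = summaries,
    baselines = baselines,
    anova = if (length(an_rows)) do.call(rbind, an_rows) else NULL,
    pairwise = if (length(pw_rows)) do.call(rbind, pw_rows) else NULL,
    groups = groups,
    manifest = cohort$manifest,
    ma_window_s = ma_window_s
  ), class = "aroma_analysis")
}

#' @export
print.aroma_analysis <- function(x, ...) {
  cat("Olfactory-stimulus biosignal analysis\n")
  cat(sprintf("  participants: %d in %d non-empty group(s)\n",
              nrow(x$manifest), sum(lengths(x$groups) > 0)))
  cat(sprintf("  index summaries: %d rows; ANOVA tables: %d; pairwise tests: %d\n",
              nrow(x$summaries),
              if (is.null(x$anova)) 0 else nrow(x$anova),
              if (is.null(x$pairwise)) 0 else nrow(x$pairwise)))
  invisible(x)
}

#' @export
summary.aroma_analysis <- function(object, alpha = 0.05, ...) {
  cat("Group sizes:\n")
  print(lengths(object$groups))
  if (!is.null(object$anova)) {
    cat("\nRepeated-measures ANOVA (stimulus factor, uncorrected p):\n")
    print(object$anova[, c("group", "index", "window", "n", "F", "p")],
          row.names = FALSE, digits = 4)
  }
  if (!is.null(object$pairwise)) {
    sig <- object$pairwise[object$pairwise$p < alpha, ]
    cat(sprintf("\nUnadjusted pairwise comparisons with p < %g: %d of %d\n",
                alpha, nrow(sig), nrow(object$pairwise)))
    if (nrow(sig)) {
      print(sig[, c("group", "index", "window", "stim_a", "stim_b",
                    "mean_diff", "p", "sig")], row.names = FALSE, digits = 4)
    }
  }
  invisible(object)
}

#' Plot method: draw an emotion map for one group
#'
#' Draws the arousal-valence map on the current device (no file output; use
#' [render_map()] to write figures with companion CSVs). Valence is the group
#' mean raw pNN50 (X-axis, origin at the group's resting mean); arousal is
#' the chosen EEG index (Y-axis).
#'
#' @param x an `aroma_analysis`.
#' @param group group key (default: first non-empty group).
#' @param arousal_index "att_minus_med", "ma_hb_ha" or "delta".
#' @param zoom zoomed view instead of full axis ranges.
#' @param ... ignored.
#' @return invisibly, the plotted `emotion_map_points`.
#' @export
plot.aroma_analysis <- function(x, group = NULL,
                                arousal_index = "att_minus_med",
                                zoom = FALSE, ...) {
  if (is.null(group)) group <- names(x$groups)[lengths(x$groups) > 0][1]
  pts <- build_map_points(x$summaries, group, arousal_index = arousal_index)
  axes <- map_axes(x, group, arousal_index)
  xlim <- if (zoom) range(pts$valence) + c(-1, 1) * 0.1 * diff(range(pts$valence))
          else c(axes$valence$min, axes$valence$max)
  ylim <- if (zoom) range(pts$arousal) + c(-1, 1) * 0.1 * diff(range(pts$arousal))
          else c(axes$arousal$min, axes$arousal$max)
  cols <- map_palette(); pchs <- map_pch()
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = "Valence (pNN50)",
                 ylab = sprintf("Arousal (%s)", arousal_index),
                 main = sprintf("Emotion map: %s", group))
  if (is.finite(axes$valence$origin))
    graphics::abline(v = axes$valence$origin, lty = 2, col = "grey40")
  if (is.finite(axes$arousal$origin))
    graphics::abline(h = axes$arousal$origin, lty = 2, col = "grey40")
  graphics::points(pts$valence, pts$arousal, col = cols[pts$stimulus],
                   pch = pchs[pts$window], cex = 1.4)
  invisible(pts)
}

# Axis pair for a group map: pNN50 origin from the group's resting means,
# arousal preset from build_axis.
map_axes <- function(x, group, arousal_index) {
  ids <- x$groups[[group]]
  rest <- x$baselines$b_avg[x$baselines$participant_id %in% ids &
                              x$baselines$index == "pnn50"]
  rest <- rest[is.finite(rest)]
  ar_data <- x$summaries$raw_mean[x$summaries$group == group &
                                    x$summaries$index == arousal_index]
  list(valence = build_axis("pnn50", rest),
       arousal = build_axis(arousal_index, ar_data[is.finite(ar_data)]))
}
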
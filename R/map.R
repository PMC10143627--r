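#' Axis configuration for the emotion map
#'
#' Encodes the axis ranges and origins of the arousal-valence map:
#' \describe{
#'   \item{att_minus_med}{fixed range -100..100, origin 0 (difference of two
#'     0-100 indexes).}
#'   \item{ma_hb_ha}{range 0..2 (the ratio's natural minimum is 0; the
#'     maximum is scaled by the data but at least 2, so the preset covers the
#'     typical range with balanced scaling); origin 1, the beta-alpha parity
#'     point of a ratio — configurable via `origin`.}
#'   \item{pnn50}{range 0..1; origin = mean resting pNN50 of the plotted
#'     participants, so the origin differs between maps and the scale left
#'     and right of it is unbalanced.}
#'   \item{delta}{raw band power is a unitless magnitude, meaningful only as
#'     relative quantity; the range is data-driven and no origin is set.}
#' }
#'
#' @param index_name one of "att_minus_med", "ma_hb_ha", "pnn50", "delta".
#' @param data numeric values used by the data-driven rules: resting pNN50
#'   values for "pnn50", plotted values for "ma_hb_ha"/"delta".
#' @param origin overrides the default origin (used mainly for "ma_hb_ha").
#' @return Object of class `axis_config`: list with `index_name`, `min`,
#'   `max`, `origin`, `origin_rule`.
#' @export
build_axis <- function(index_name, data = numeric(0), origin = NULL) {
  ax <- switch(index_name,
    att_minus_med = list(min = -100, max = 100, origin = 0,
                         origin_rule = "fixed"),
    ma_hb_ha = {
      mx <- if (length(data) && max(data, na.rm = TRUE) > 2)
        max(data, na.rm = TRUE) else 2
      list(min = 0, max = mx, origin = 1, origin_rule = "fixed")
    },
    pnn50 = {
      stop_if_not(length(data) >= 1,
                  "pnn50 axis needs resting-condition values to set its origin")
      list(min = 0, max = 1, origin = mean(data, na.rm = TRUE),
           origin_rule = "resting_mean")
    },
    delta = {
      rng <- if (length(data)) range(data, na.rm = TRUE) else c(0, 1)
      if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
      list(min = rng[1], max = rng[2], origin = NA_real_,
           origin_rule = "data_max_scaled")
    },
    stop(sprintf("unsupported emotion-map index: %s", index_name), call. = FALSE)
  )
  if (!is.null(origin)) ax$origin <- origin
  stop_if_not(ax$min < ax$max, "axis min must be below max")
  if (is.finite(ax$origin)) {
    stop_if_not(ax$origin >= ax$min && ax$origin <= ax$max,
                "axis origin must lie inside [min, max]")
  }
  structure(c(list(index_name = index_name), ax), class = "axis_config")
}

#' Emotion-map points for one participant group
#'
#' One point per stimulus and exposure window (7 stimuli x 3 windows = 21
#' points): the group mean of the raw per-window index means — valence from
#' pNN50 on X, the chosen arousal index on Y. Raw (unnormalized) window means
#' are used so that the resting-mean origin construction applies; the
#' normalized changes remain the statistics module's input.
#'
#' @param raw_means data.frame with columns `participant_id`, `group`,
#'   `stimulus`, `window`, `index`, `raw_mean` (as produced by
#'   [aroma_analysis()], component `summaries`).
#' @param group group key to plot.
#' @param valence_index valence index name (default "pnn50").
#' @param arousal_index arousal index name ("att_minus_med", "ma_hb_ha" or
#'   "delta").
#' @return data.frame of class `emotion_map_points`: `stimulus`, `window`,
#'   `valence`, `arousal`, `group`, `n` (participants averaged). Stimuli with
#'   no defined mean are omitted with a message.
#' @export
build_map_points <- function(raw_means, group,
                             valence_index = "pnn50",
                             arousal_index = "att_minus_med") {
  need <- c("participant_id", "group", "stimulus", "window", "index", "raw_mean")
  stop_if_not(all(need %in% names(raw_means)),
              "raw_means missing columns: %s",
              paste(setdiff(need, names(raw_means)), collapse = ", "))
  sub <- raw_means[raw_means$group == group & raw_means$window != "baseline", ]
  stop_if_not(nrow(sub) > 0, "no data for group %s", group)
  windows <- c("all", "first_half", "latter_half")
  stims <- stimulus_table()$name
  rows <- list()
  for (s in stims) {
    for (w in windows) {
      v <- sub$raw_mean[sub$stimulus == s & sub$window == w &
                          sub$index == valence_index]
      a <- sub$raw_mean[sub$stimulus == s & sub$window == w &
                          sub$index == arousal_index]
      vm <- mean(v, na.rm = TRUE)
      am <- mean(a, na.rm = TRUE)
      if (!is.finite(vm) || !is.finite(am)) {
        message(sprintf("build_map_points: %s/%s omitted (no defined mean)", s, w))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        stimulus = s, window = w, valence = vm, arousal = am,
        group = group, n = sum(is.finite(v)), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("emotion_map_points", "data.frame")
  out
}

#' Classify emotion-map points into circumplex quadrants
#'
#' Strict comparison against the axis origins: valence above its origin is
#' high valence (HV), arousal above its origin high arousal (HA); equality on
#' either axis gives "on_axis". LAHV (low arousal, high valence) is the lower
#' right quadrant, LALV the lower left.
#'
#' @param valence,arousal numeric vectors (or an `emotion_map_points`
#'   data.frame as first argument).
#' @param valence_axis,arousal_axis `axis_config` objects with finite origins.
#' @return character vector: "HAHV", "HALV", "LAHV", "LALV" or "on_axis".
#' @export
classify_quadrant <- function(valence, arousal = NULL, valence_axis, arousal_axis) {
  if (is.data.frame(valence)) {
    arousal <- valence$arousal
    valence <- valence$valence
  }
  stop_if_not(is.finite(valence_axis$origin) && is.finite(arousal_axis$origin),
              "both axis origins must be finite for quadrant classification")
  ox <- valence_axis$origin
  oy <- arousal_axis$origin
  ifelse(valence == ox | arousal == oy, "on_axis",
    ifelse(arousal > oy,
      ifelse(valence > ox, "HAHV", "HALV"),
      ifelse(valence > ox, "LAHV", "LALV")))
}

map_palette <- function() {
  stats::setNames(
    c("#E69F00", "#9467BD", "#56B4E9", "#8C564B", "#E377C2", "#2CA02C", "#D62728"),
    stimulus_table()$name
  )
}

map_pch <- function() {
  c(all = 16, first_half = 17, latter_half = 15)  # circle, triangle, square
}

#' Render an emotion map to a figure file with a companion CSV
#'
#' Full-scale view uses the axis ranges; the zoom view uses the data extent
#' padded by 10%. Seven stimulus colors and three window marker shapes
#' (circle = all, triangle = first half, square = latter half). The companion
#' CSV (same path, extension .csv) holds exactly the plotted coordinates plus
#' the quadrant classification when both origins are defined.
#'
#' @param points `emotion_map_points` (from [build_map_points()]).
#' @param valence_axis,arousal_axis `axis_config` objects.
#' @param zoom logical: zoomed view instead of full scale.
#' @param out_path figure path ending in .png or .pdf.
#' @return invisibly, the companion CSV path.
#' @export
render_map <- function(points, valence_axis, arousal_axis, zoom = FALSE,
                       out_path) {
  stop_if_not(nrow(points) >= 1, "no points to plot")
  ext <- tolower(tools::file_ext(out_path))
  stop_if_not(ext %in% c("png", "pdf"), "out_path must end in .png or .pdf")
  dir <- dirname(out_path)
  stop_if_not(dir.exists(dir) || dir.create(dir, recursive = TRUE),
              "cannot create output directory %s", dir)

  if (zoom) {
    pad <- function(r) r + c(-1, 1) * 0.1 * max(diff(r), .Machine$double.eps)
    xlim <- pad(range(points$valence))
    ylim <- pad(range(points$arousal))
  } else {
    xlim <- c(valence_axis$min, valence_axis$max)
    ylim <- c(arousal_axis$min, arousal_axis$max)
  }
  cols <- map_palette()
  pchs <- map_pch()

  if (ext == "png") grDevices::png(out_path, width = 900, height = 700, res = 120)
  else grDevices::pdf(out_path, width = 7.5, height = 6)
  on.exit(grDevices::dev.off())
  graphics::plot(NA, xlim = xlim, ylim = ylim,
                 xlab = sprintf("Valence (%s)", valence_axis$index_name),
                 ylab = sprintf("Arousal (%s)", arousal_axis$index_name),
                 main = sprintf("Emotion map: %s%s", points$group[1],
                                if (zoom) " (zoom)" else ""))
  if (is.finite(valence_axis$origin))
    graphics::abline(v = valence_axis$origin, lty = 2, col = "grey40")
  if (is.finite(arousal_axis$origin))
    graphics::abline(h = arousal_axis$origin, lty = 2, col = "grey40")
  graphics::points(points$valence, points$arousal,
                   col = cols[points$stimulus], pch = pchs[points$window],
                   cex = 1.4)
  graphics::legend("topleft", legend = names(cols), col = cols, pch = 16,
                   cex = 0.7, title = "Stimulus", bty = "n")
  graphics::legend("topright", legend = names(pchs), pch = pchs, cex = 0.7,
                   title = "Window", bty = "n")

  csv_path <- sub(sprintf("\\.%s$", ext), ".csv", out_path)
  out <- as.data.frame(points)
  out$marker <- unname(c(all = "circle", first_half = "triangle",
                         latter_half = "square")[out$window])
  out$color <- unname(cols[out$stimulus])
  if (is.finite(valence_axis$origin) && is.finite(arousal_axis$origin)) {
    out$quadrant <- classify_quadrant(points$valence, points$arousal,
                                      valence_axis, arousal_axis)
  }
  utils::write.csv(out, csv_path, row.names = FALSE)
  invisible(csv_path)
}
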
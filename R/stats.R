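#' One-factor repeated-measures ANOVA
#'
#' The within-subject design of the study: the same participants are measured
#' under all k stimuli, so the total sum of squares partitions into subject,
#' condition and error components and `F = MS_conditions / MS_error` with
#' `df = (k - 1, (n - 1)(k - 1))`. The F test is fitted via [stats::aov()]
#' with an `Error(participant)` stratum. The p-value is reported uncorrected
#' for sphericity, mirroring the study's analysis; the Greenhouse-Geisser
#' epsilon and corrected p-value are reported alongside for transparency.
#'
#' Rows with any missing cell are removed (listwise deletion); the number of
#' removed rows is attached as attribute `n_dropped`.
#'
#' @param m numeric matrix, participants x conditions (>= 3 complete rows,
#'   >= 2 columns).
#' @return Object of class `rm_anova`: list with `F`, `df_num`, `df_den`,
#'   `p`, `gg_epsilon`, `p_gg`, `n`, `k` and the SS partition.
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 3, 5, 3, 4, 6), nrow = 3, byrow = TRUE)
#' rm_anova(m)  # F = 49 on (2, 4) df
#' @export
rm_anova <- function(m) {
  m <- as.matrix(m)
  stop_if_not(is.numeric(m) && ncol(m) >= 2, "m must be numeric with >= 2 conditions")
  complete <- stats::complete.cases(m)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message(sprintf("rm_anova: %d incomplete row(s) removed", n_dropped))
  }
  m <- m[complete, , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  stop_if_not(n >= 3, "insufficient complete cases (need >= 3 participants)")

  long <- data.frame(
    y = as.vector(m),
    subj = factor(rep(seq_len(n), times = k)),
    cond = factor(rep(seq_len(k), each = n))
  )
  fit <- stats::aov(y ~ cond + Error(subj), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  ss_cond <- tab["cond", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df_num <- as.integer(tab["cond", "Df"])
  df_den <- as.integer(tab["Residuals", "Df"])
  ms_err <- ss_err / df_den
  scale_ss <- max(sum(long$y^2), 1)
  if (ms_err <= 1e-12 * scale_ss) {
    warning("zero error mean square; p reported as 0")
    degenerate_effect <- ss_cond > 1e-12 * scale_ss
    Fv <- if (degenerate_effect) Inf else 0
    p <- if (degenerate_effect) 0 else 1
  } else {
    Fv <- tab["cond", "F value"]
    p <- tab["cond", "Pr(>F)"]
  }

  # Greenhouse-Geisser epsilon from the double-centered covariance of columns
  S <- stats::cov(m)
  dc <- S - outer(rowMeans(S), rep(1, k)) - outer(rep(1, k), colMeans(S)) + mean(S)
  eps <- sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
  eps <- min(1, max(1 / (k - 1), eps))
  p_gg <- if (is.finite(Fv)) {
    stats::pf(Fv, df_num * eps, df_den * eps, lower.tail = FALSE)
  } else {
    0
  }

  structure(list(
    F = Fv, df_num = df_num, df_den = df_den, p = p,
    gg_epsilon = eps, p_gg = p_gg, n = n, k = k,
    ss_conditions = ss_cond, ss_error = ss_err,
    ss_subjects = summary(fit)[["Error: subj"]][[1]]["Residuals", "Sum Sq"]
  ), class = "rm_anova", n_dropped = n_dropped)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("Repeated-measures ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_num, x$df_den, x$F, x$p))
  cat(sprintf("  (n = %d subjects, k = %d conditions; GG epsilon = %.3f, p_GG = %.4g)\n",
              x$n, x$k, x$gg_epsilon, x$p_gg))
  invisible(x)
}

#' Unadjusted post hoc pairwise comparisons
#'
#' Paired two-sided t tests on all `k(k-1)/2` condition pairs (21 pairs for
#' the 7 stimuli) with no p-value adjustment, as in the study's post hoc
#' analysis. Significance flags are set at the 0.05 / 0.01 / 0.001 levels.
#' A zero-variance difference vector with a nonzero mean is degenerate and
#' reported with `p = 0` and a warning; with zero mean, `t = 0` and `p = 1`.
#'
#' @param m numeric matrix, participants x conditions; column names label the
#'   stimuli. Incomplete rows are removed listwise.
#' @return data.frame with one row per pair: `stim_a`, `stim_b`, `mean_diff`
#'   (a minus b), `t`, `df`, `p`, `sig` ("", "*", "**", "***").
#' @export
posthoc_pairwise <- function(m) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- paste0("C", seq_len(ncol(m)))
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  k <- ncol(m)
  stop_if_not(n >= 3, "insufficient complete cases (need >= 3 participants)")
  pairs <- utils::combn(k, 2)
  out <- data.frame(
    stim_a = colnames(m)[pairs[1, ]],
    stim_b = colnames(m)[pairs[2, ]],
    mean_diff = NA_real_, t = NA_real_, df = n - 1L, p = NA_real_,
    sig = "", stringsAsFactors = FALSE
  )
  for (j in seq_len(ncol(pairs))) {
    d <- m[, pairs[1, j]] - m[, pairs[2, j]]
    out$mean_diff[j] <- mean(d)
    if (stats::sd(d) == 0) {
      if (mean(d) == 0) {
        out$t[j] <- 0
        out$p[j] <- 1
      } else {
        warning(sprintf("degenerate pair %s vs %s: zero-variance differences",
                        out$stim_a[j], out$stim_b[j]))
        out$t[j] <- Inf * sign(mean(d))
        out$p[j] <- 0
      }
    } else {
      tt <- stats::t.test(m[, pairs[1, j]], m[, pairs[2, j]], paired = TRUE)
      out$t[j] <- unname(tt$statistic)
      out$p[j] <- tt$p.value
    }
  }
  out$sig <- ifelse(out$p < 0.001, "***",
             ifelse(out$p < 0.01, "**",
             ifelse(out$p < 0.05, "*", "")))
  out
}
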
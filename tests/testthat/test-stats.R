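test_that("repeated-measures ANOVA matches the hand-computed SS partition", {
  # 3 subjects x 3 conditions; by hand: SS_total = 176/9, SS_subj = 74/9,
  # SS_cond = 98/9, SS_err = 4/9 -> F = (49/9)/(1/9) = 49 on (2, 4) df
  m <- matrix(c(1, 2, 3,
                2, 3, 5,
                3, 4, 6), nrow = 3, byrow = TRUE)
  a <- rm_anova(m)
  expect_equal(a$F, 49, tolerance = 1e-10)
  expect_identical(c(a$df_num, a$df_den), c(2L, 4L))
  expect_equal(a$p, stats::pf(49, 2, 4, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(a$ss_conditions, 98 / 9, tolerance = 1e-10)
  expect_equal(a$ss_error, 4 / 9, tolerance = 1e-10)
  expect_equal(a$ss_subjects, 74 / 9, tolerance = 1e-10)
})

test_that("degenerate and small designs are handled", {
  m_eq <- matrix(5, nrow = 4, ncol = 3)
  expect_warning(a <- rm_anova(m_eq), "zero error")
  expect_identical(a$F, 0)
  expect_identical(a$p, 1)
  expect_error(rm_anova(matrix(rnorm(4), 2, 2)), "insufficient")
  expect_error(rm_anova(matrix(rnorm(5), 5, 1)), "2 conditions")
})

test_that("for two conditions F equals the squared paired t statistic", {
  set.seed(3)
  m <- matrix(rnorm(20), nrow = 10, ncol = 2)
  a <- rm_anova(m)
  tt <- stats::t.test(m[, 1], m[, 2], paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
})

test_that("incomplete rows are removed listwise with a message", {
  set.seed(8)
  m <- matrix(rnorm(21), nrow = 7, ncol = 3)
  m[2, 1] <- NA
  expect_message(a <- rm_anova(m), "1 incomplete")
  expect_identical(a$n, 6L)
  expect_identical(attr(a, "n_dropped"), 1L)
})

test_that("statistics are invariant to participant row order", {
  set.seed(12)
  m <- matrix(rnorm(7 * 15), nrow = 15, ncol = 7)
  a1 <- rm_anova(m)
  a2 <- rm_anova(m[sample(15), ])
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$gg_epsilon, a2$gg_epsilon, tolerance = 1e-10)
  p1 <- posthoc_pairwise(m)
  p2 <- posthoc_pairwise(m[sample(15), ])
  expect_equal(p1$t, p2$t, tolerance = 1e-10)
})

test_that("pairwise comparisons match the textbook paired t", {
  # 4 x 2 fixed case: d = (1,2,2,3), mean 2, sd sqrt(2/3) -> t = sqrt(24)
  m <- cbind(a = c(2, 4, 5, 7), b = c(1, 2, 3, 4))
  pw <- posthoc_pairwise(m)
  expect_identical(nrow(pw), 1L)
  expect_equal(pw$t, sqrt(24), tolerance = 1e-10)
  expect_identical(pw$df, 3L)
  expect_equal(pw$p, 2 * stats::pt(-sqrt(24), 3), tolerance = 1e-10)
  expect_equal(pw$mean_diff, 2)
})

test_that("pairwise table covers all 21 stimulus pairs, unadjusted", {
  set.seed(4)
  m <- matrix(rnorm(15 * 7), nrow = 15, ncol = 7,
              dimnames = list(NULL, stimulus_table()$name))
  pw <- posthoc_pairwise(m)
  expect_identical(nrow(pw), 21L)
  expect_identical(anyDuplicated(paste(pw$stim_a, pw$stim_b)), 0L)
  # oracle: base pairwise.t.test with no adjustment
  long <- data.frame(y = as.vector(m),
                     g = factor(rep(colnames(m), each = 15),
                                levels = colnames(m)))
  or <- stats::pairwise.t.test(long$y, long$g, paired = TRUE,
                               p.adjust.method = "none")$p.value
  for (j in seq_len(nrow(pw))) {
    pij <- or[pw$stim_b[j], pw$stim_a[j]]
    if (is.na(pij)) pij <- or[pw$stim_a[j], pw$stim_b[j]]
    expect_equal(pw$p[j], pij, tolerance = 1e-9)
  }
})

test_that("degenerate pairs are flagged; shifted columns give exact mean_diff", {
  base <- rnorm(6)
  m <- cbind(a = base, b = base, c = base + 2, d = rnorm(6))
  w <- capture_warnings(pw <- posthoc_pairwise(m))
  expect_true(any(grepl("degenerate", w)))
  ab <- pw[pw$stim_a == "a" & pw$stim_b == "b", ]
  expect_identical(ab$mean_diff, 0)
  expect_identical(ab$t, 0)
  expect_identical(ab$p, 1)
  ac <- pw[pw$stim_a == "a" & pw$stim_b == "c", ]
  expect_identical(ac$mean_diff, -2)
  expect_identical(ac$p, 0)
  expect_true(all(pw$sig[pw$p < 0.001] == "***"))
})

test_that("injected stimulus effects surface as the most significant pairs", {
  # one condition shifted upward: its pairwise tests should dominate
  set.seed(99)
  hits <- integer(7)
  for (r in 1:20) {
    m <- matrix(rnorm(15 * 7), nrow = 15, ncol = 7,
                dimnames = list(NULL, stimulus_table()$name))
    m[, "lavender"] <- m[, "lavender"] + 1
    pw <- posthoc_pairwise(m)
    sig <- pw[pw$p < 0.05, ]
    for (s in stimulus_table()$name) {
      hits[match(s, stimulus_table()$name)] <-
        hits[match(s, stimulus_table()$name)] +
        sum(sig$stim_a == s | sig$stim_b == s)
    }
  }
  expect_identical(stimulus_table()$name[which.max(hits)], "lavender")
})
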
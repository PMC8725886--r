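toy_epochs <- function(samples, colors = NULL, locations = NULL,
                       fs = 1000) {
  time <- seq(-0.5, 2.5, by = 1 / fs)
  if (is.null(dim(samples)))
    samples <- matrix(samples, 1, length(time))
  if (is.null(colors)) colors <- rep("blue", nrow(samples))
  if (is.null(locations)) locations <- rep("top", nrow(samples))
  epoch_set(time, samples, colors, locations, fs = fs)
}

test_that("percent signal change normalizes against the baseline", {
  time <- seq(-0.5, 2.5, by = 1 / 1000)
  flat <- toy_epochs(rep(1000, length(time)))
  out <- percent_signal_change(flat)
  expect_true(all(out$samples == 0))
  expect_equal(out$baseline, 1000)
  x <- rep(1000, length(time)); x[time > 0.8 & time < 1] <- 600
  out2 <- percent_signal_change(toy_epochs(x))
  expect_equal(min(out2$samples), -40)
  # scale invariance in device units
  out3 <- percent_signal_change(toy_epochs(3.7 * x))
  expect_equal(out3$samples, out2$samples, tolerance = 1e-12)
  # missing baseline invalidates the trial
  x4 <- x; x4[time < 0] <- NaN
  out4 <- percent_signal_change(toy_epochs(x4))
  expect_false(out4$baseline_valid)
  expect_true(all(is.nan(out4$samples)))
})

test_that("QC enforces the per-condition and 50% rules", {
  des <- build_exp2_design()
  time <- seq(-0.5, 2.5, by = 1 / 1000)
  mk <- function(invalidate) {
    smp <- matrix(1000, nrow(des), length(time))
    for (i in invalidate) smp[i, which(time > 0)[1:50]] <- NaN
    epoch_set(time, smp, des$color, des$location)
  }
  qc_all <- qc_trials_and_subjects(mk(integer(0)))
  expect_true(qc_all$included)
  expect_equal(qc_all$n_valid, 60L)
  # all blue-top trials invalid -> excluded despite > 50% valid overall
  bt <- which(des$color == "blue" & des$location == "top")
  qc_bt <- qc_trials_and_subjects(mk(bt))
  expect_false(qc_bt$included)
  # 29/60 valid with >= 1 per condition -> excluded by the 50% rule
  keep <- unlist(lapply(split(seq_len(60),
                              paste(des$color, des$location)), `[`, 1))
  extra <- setdiff(seq_len(60), keep)[1:17]   # 12 + 17 = 29 valid
  qc29 <- qc_trials_and_subjects(mk(setdiff(seq_len(60),
                                            c(keep, extra))))
  expect_equal(qc29$n_valid, 29L)
  expect_false(qc29$included)
})

test_that("condition waveforms average point-wise before the minimum", {
  time <- seq(-0.5, 2.5, by = 1 / 1000)
  base <- rep(0, length(time))
  tr1 <- base; tr1[time > 0.9 & time < 1] <- -30
  tr2 <- base; tr2[time > 0.9 & time < 1] <- -50
  got <- condition_waveform_and_plrmin(rbind(tr1, tr2), time)
  expect_equal(got$plr_min, -40)
  one <- condition_waveform_and_plrmin(tr1, time)
  expect_equal(one$plr_min, -30)
  # dilation-only trace still returns its minimum (>= 0)
  up <- base + 5
  expect_gte(condition_waveform_and_plrmin(up, time)$plr_min, 0)
  # min of the mean >= mean of the per-trial minima
  set.seed(41)
  for (i in 1:20) {
    m <- matrix(rnorm(5 * length(time)), 5)
    mm <- condition_waveform_and_plrmin(m, time)$plr_min
    per <- apply(m[, time >= 0 & time <= 2], 1, min)
    expect_gte(mm + 1e-12, mean(per))
  }
})

test_that("rm_anova_3x4 reproduces a classical decomposition", {
  set.seed(42)
  y <- array(rnorm(4 * 3 * 4, sd = 2), c(4, 3, 4)) +
    array(rep(c(-40, -38, -44), each = 1), c(4, 3, 4)) +
    rnorm(4)                                # subject offsets recycle over y
  an <- rm_anova_3x4(y)
  o <- rm_anova_oracle(y)
  expect_equal(an$F[1], o$F_a, tolerance = 1e-8)
  expect_equal(an$F[2], o$F_b, tolerance = 1e-8)
  expect_equal(an$F[3], o$F_ab, tolerance = 1e-8)
  expect_equal(an$df1, c(2, 3, 6))
  expect_equal(an$df2, c(6, 9, 18))
  expect_true(all(an$epsilon > 0 & an$epsilon <= 1))
  expect_true(all(an$df1_gg <= an$df1 + 1e-12))
  expect_error(rm_anova_3x4(y[1:2, , ]), "3 subjects")
})

test_that("an additive color effect loads on the color term only", {
  set.seed(43)
  n <- 12
  y <- array(rnorm(n * 12, sd = 1), c(n, 3, 4))
  y[, 3, ] <- y[, 3, ] - 6                  # strong blue effect
  an <- rm_anova_3x4(y)
  expect_lt(an$p[an$effect == "color"], 1e-6)
  expect_gt(an$p[an$effect == "location"], 0.01)
  expect_gt(an$pes[1], an$pes[2])
})

test_that("difference scores are antisymmetric and FDR-adjusted over 6", {
  set.seed(44)
  y <- array(rnorm(15 * 12, -40, 3), c(15, 3, 4),
             dimnames = list(NULL, c("red", "green", "blue"),
                             c("top", "bottom", "left", "right")))
  ds <- difference_score_tests(y)
  expect_equal(nrow(ds), 6L)
  expect_equal(ds$p_fdr, bh_fdr(ds$p, 0.05)$p_adj)
  # reversing a pair flips the sign exactly
  y2 <- y; y2[, , "top"] <- y[, , "bottom"]; y2[, , "bottom"] <- y[, , "top"]
  ds2 <- difference_score_tests(y2)
  vert <- ds$orientation == "vertical"
  expect_equal(ds2$t[vert], -ds$t[vert], tolerance = 1e-12)
  expect_equal(ds2$t[!vert], ds$t[!vert], tolerance = 1e-12)
  # degenerate: identical conditions
  yc <- array(-40, c(5, 3, 4),
              dimnames = dimnames(y))
  expect_warning(dsc <- difference_score_tests(yc), "degenerate")
  expect_true(all(dsc$mean_diff == 0))
  expect_true(all(dsc$t == 0))
})
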
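test_that("fit_gamma recovers known exponents", {
  v <- seq(0, 255, by = 3)
  fit <- fit_gamma(v, (v / 255)^2.2)
  expect_equal(fit$gamma, 2.2, tolerance = 0.01)
  expect_equal(fit$scale, 1, tolerance = 0.01)
  lin <- fit_gamma(v, v / 255)
  expect_equal(lin$gamma, 1, tolerance = 0.01)
  scaled <- fit_gamma(v, 187 * (v / 255)^2.24)
  expect_equal(scaled$gamma, 2.24, tolerance = 0.01)
  expect_equal(scaled$scale, 187, tolerance = 0.5)
  expect_error(fit_gamma(c(0, 255), c(0, 1)), "4 distinct")
  expect_error(fit_gamma(c(0, 50, 100, 150), c(0, .1, .2, .3)), "high")
  expect_error(fit_gamma(v, rep(0, length(v))), "all-zero")
  expect_warning(fit_gamma(c(0, 64, 128, 255), c(0, 0.5, 0.1, 1)),
                 "non-monotone")
})

test_that("gamma_transform maps endpoints and midpoints correctly", {
  fr <- array(0, c(2, 2, 3))
  fr[1, 1, ] <- 255; fr[1, 2, ] <- 128
  lum <- gamma_transform(fr, gamma_params())
  expect_equal(lum[2, 1, 1], 0)                       # v = 0 -> 0
  expect_equal(lum[1, 1, 3], 1)                       # v = 255, unit scale
  expect_equal(lum[1, 2, 3], (128 / 255)^2.22, tolerance = 1e-12)
  expect_equal(lum[1, 2, 3], 0.2165, tolerance = 1e-3)
  # strictly monotone per channel
  ramp <- array(rep(0:255, 3), c(256, 1, 3))
  out <- gamma_transform(ramp)
  for (c in 1:3) expect_true(all(diff(out[, 1, c]) > 0))
})

test_that("CIELAB conversion follows CIE polarity and matches base R", {
  px <- function(r, g, b) array(c(r, g, b), c(1, 1, 3))
  white <- rgb_to_cielab(px(255, 255, 255))
  expect_equal(white[1, 1, 1], 100, tolerance = 0.01)
  expect_lt(abs(white[1, 1, 2]), 0.5)
  expect_lt(abs(white[1, 1, 3]), 0.5)
  expect_equal(rgb_to_cielab(px(0, 0, 0))[1, 1, 1], 0, tolerance = 0.01)
  blue <- rgb_to_cielab(px(0, 0, 255))
  expect_lt(blue[1, 1, 3], 0)               # negative b* = blue
  # any gray is near-neutral
  for (v in c(32, 96, 200)) {
    g <- rgb_to_cielab(px(v, v, v))
    expect_lt(abs(g[1, 1, 2]), 0.5)
    expect_lt(abs(g[1, 1, 3]), 0.5)
  }
  # oracle: base R sRGB -> Lab (slightly different whitepoint rounding)
  set.seed(3)
  rgb <- matrix(sample(0:255, 30, TRUE), ncol = 3)
  ours <- rgb_to_cielab(array(rgb, c(10, 1, 3)))
  ref <- grDevices::convertColor(rgb / 255, from = "sRGB", to = "Lab")
  expect_lt(max(abs(matrix(ours, ncol = 3) - ref)), 1.5)
})

test_that("gaze windows are positioned and NaN-padded correctly", {
  H <- 1080; W <- 1920
  fr <- array(seq_len(H * W * 3), c(H, W, 3))
  # screen center: the 700 px window fits fully inside 1920 x 1080
  w <- extract_gaze_window(fr, c(W / 2, H / 2), half = 350)
  expect_equal(sum(is.nan(w)), 0)
  # near the top edge the overhang is NaN rows only
  wt <- extract_gaze_window(fr, c(W / 2, 100), half = 350)
  nan_rows <- apply(is.nan(wt[, , 1]), 1, all)
  nan_cols <- apply(is.nan(wt[, , 1]), 2, all)
  expect_equal(sum(nan_cols), 0)
  expect_equal(sum(nan_rows), 250)         # rows -350..-101 off-screen
  # gaze pixel lands at 0-based window index [350, 350]
  expect_equal(w[351, 351, 1], fr[H / 2 + 1, W / 2 + 1, 1])
  # top-left corner: exactly 25% of cells valid
  w0 <- extract_gaze_window(fr, c(0, 0), half = 350)
  expect_equal(mean(!is.nan(w0[, , 1])), 0.25)
  # missing or off-screen gaze
  expect_true(all(is.nan(extract_gaze_window(fr, c(NaN, 5), half = 350))))
  expect_true(all(is.nan(extract_gaze_window(fr, c(-5, 5), half = 350))))
})

test_that("block_downsample averages blocks and ignores NaN", {
  w <- array(3.5, c(700, 700, 3))
  out <- block_downsample(w, 10)
  expect_equal(dim(out), c(70L, 70L, 3L))
  expect_true(all(out == 3.5))
  # half-NaN block keeps the valid mean
  w2 <- array(7, c(10, 10, 1))
  w2[1:5, , 1] <- NaN
  expect_equal(block_downsample(w2, 10)[1, 1, 1], 7)
  w3 <- array(NaN, c(10, 10, 1))
  expect_true(is.nan(block_downsample(w3, 10)[1, 1, 1]))
  expect_error(block_downsample(array(0, c(700, 701, 3)), 10), "divide")
  # oracle on random data with scattered NaN
  set.seed(5)
  w4 <- array(rnorm(40 * 40 * 2), c(40, 40, 2))
  w4[sample(length(w4), 300)] <- NaN
  got <- block_downsample(w4, 10)
  for (i in 1:4) for (j in 1:4) for (c in 1:2) {
    blk <- w4[(i - 1) * 10 + 1:10, (j - 1) * 10 + 1:10, c]
    expect_equal(got[i, j, c], mean(blk[is.finite(blk)]), tolerance = 1e-12)
  }
})

test_that("window + downsample of an all-ones frame marks valid coverage", {
  fr <- array(1, c(60, 60, 3))
  w <- extract_gaze_window(fr, c(10, 10), half = 30)
  out <- block_downsample(w, 10)
  # NaN-ignoring mean is exactly 1 wherever any cell of the block is valid
  valid_frac <- block_downsample(is.finite(w) * 1, 10)
  expect_true(all(out[valid_frac > 0] == 1))
  expect_true(all(is.nan(out[valid_frac == 0])))
})

test_that("nan_fraction_map tracks off-screen coverage over time", {
  fr <- frame_stack(array(128, c(4, 100, 100, 3)), fs = 12)
  stk <- gaze_window_stack(fr, rep(50, 4), rep(50, 4), half = 20,
                           factor = 1, channel_space = "none")
  expect_true(all(nan_fraction_map(stk) == 0))
  stk2 <- gaze_window_stack(fr, c(50, 50, 50, NaN), c(50, 50, 50, 5),
                            half = 20, factor = 1, channel_space = "none")
  nm <- nan_fraction_map(stk2)
  expect_equal(nm[40, 40], 0.25)           # one all-NaN frame of four
  # gaze pinned to the top-left corner: upper-left cells lose more frames
  stk3 <- gaze_window_stack(fr, rep(0, 4), rep(0, 4), half = 20,
                            factor = 1, channel_space = "none")
  nm3 <- nan_fraction_map(stk3)
  expect_gt(nm3[1, 1], nm3[40, 40])
  expect_equal(nm3[1, 1], 1)               # above the screen entirely
  expect_equal(nm3[40, 40], 0)
})
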
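make_trace <- function(value, fs = 300) pupil_trace(value, fs)

test_that("select_eye prefers less missing data with left tie-break", {
  n <- 100
  left <- make_trace(c(rep(NaN, 10), rep(5, 90)))
  right <- make_trace(c(rep(NaN, 20), rep(5, 80)))
  expect_identical(attr(select_eye(left, right), "eye"), "left")
  expect_identical(attr(select_eye(right, left), "eye"), "right")
  tie <- make_trace(c(rep(NaN, 10), rep(4, 90)))
  expect_identical(attr(select_eye(left, tie), "eye"), "left")
  dead <- make_trace(rep(NaN, n))
  expect_error(select_eye(dead, dead), "fully missing")
  expect_error(select_eye(left, make_trace(rep(5, 50))), "equal length")
})

test_that("missing_fraction counts invalid samples", {
  expect_equal(missing_fraction(make_trace(rep(1, 100))), 0)
  expect_equal(missing_fraction(make_trace(c(rep(NaN, 25), rep(1, 75)))),
               0.25)
  expect_equal(missing_fraction(make_trace(rep(NaN, 10))), 1)
  expect_error(missing_fraction(make_trace(numeric(0))), "empty")
})

test_that("velocity outlier removal repairs spikes in two passes", {
  expect_warning(out <- remove_velocity_outliers(make_trace(rep(7, 50))),
                 "zero velocity variance")
  expect_equal(out$value, rep(7, 50))
  expect_error(remove_velocity_outliers(make_trace(c(1, 2))), "3 valid")

  fs <- 300
  t <- (0:(10 * fs - 1)) / fs
  clean <- 1000 + 30 * sin(2 * pi * 0.4 * t)
  x <- clean
  x[1500] <- x[1500] + 100 * 30          # 100x amplitude spike
  tr <- remove_velocity_outliers(make_trace(x))
  # brute-force velocity check against the pre-spike series
  vmax_clean <- max(abs(diff(clean) * fs))
  vmax_fixed <- max(abs(diff(tr$value) * fs))
  expect_lt(abs(tr$value[1500] - clean[1500]), 5)
  expect_lte(vmax_fixed, vmax_clean * 1.05)
  # idempotent on its own output for this fixture
  tr2 <- remove_velocity_outliers(tr)
  expect_equal(sum(attr(tr2, "n_flagged")), 0)
})

test_that("blink detection respects the 50-500 ms duration bounds", {
  p <- preprocess_params()
  gap <- function(ms, fs = 300) {
    x <- rep(100, 3 * fs)
    x[fs:(fs + round(ms * fs / 1000) - 1)] <- NaN
    make_trace(x, fs)
  }
  expect_equal(nrow(detect_blinks(gap(100), p)), 1L)   # 30 samples
  expect_equal(detect_blinks(gap(100), p)$duration_ms, 100)
  expect_equal(nrow(detect_blinks(gap(600), p)), 0L)   # dropout
  expect_equal(nrow(detect_blinks(gap(30), p)), 0L)    # too short
  expect_equal(nrow(detect_blinks(make_trace(rep(1, 100)), p)), 0L)
})

test_that("blink repair interpolates across partial-closure ramps", {
  fs <- 300
  t <- (0:(6 * fs - 1)) / fs
  clean <- 1000 + 25 * sin(2 * pi * 0.3 * t)
  x <- clean
  ramp <- round(0.020 * fs)
  s <- 900; len <- 60                      # 200 ms blink
  x[(s - ramp):(s - 1)] <- x[(s - ramp):(s - 1)] * seq(1, 0.6, length.out = ramp)
  x[(s + len):(s + len + ramp - 1)] <-
    x[(s + len):(s + len + ramp - 1)] * seq(0.6, 1, length.out = ramp)
  x[s:(s + len - 1)] <- NaN
  tr <- make_trace(x, fs)
  rep_tr <- repair_blinks(tr, detect_blinks(tr))
  expect_equal(missing_fraction(rep_tr), 0)
  span <- (s - ramp):(s + len + ramp - 1)
  expect_lt(max(abs(rep_tr$value[span] - clean[span])),
            (max(clean) - min(clean)) / 10)
  # untouched outside the padded interval
  pad <- round(0.050 * fs)
  outside <- setdiff(seq_along(x), (s - ramp - pad):(s + len + ramp + pad))
  expect_identical(rep_tr$value[outside], x[outside])
})

test_that("blink repair handles degenerate positions", {
  x <- rep(50, 900); x[300:360] <- NaN
  tr <- make_trace(x)
  out <- repair_blinks(tr, detect_blinks(tr))
  expect_equal(out$value, rep(50, 900))   # constant stays constant
  x2 <- rep(80, 900); x2[1:30] <- NaN     # truncated at sample 0
  tr2 <- make_trace(x2)
  out2 <- repair_blinks(tr2, detect_blinks(tr2))
  expect_equal(out2$value[1:30], rep(80, 30))
})

test_that("downsampling takes bin means and respects NaN bins", {
  expect_equal(downsample_trace(make_trace(rep(5, 300)), 12)$value,
               rep(5, 12))
  ramp <- make_trace(0:299)
  expect_equal(downsample_trace(ramp, 12)$value[1], mean(0:24))
  x <- rep(2, 300); x[26:50] <- NaN       # second bin fully invalid
  d <- downsample_trace(make_trace(x), 12)
  expect_true(is.nan(d$value[2]))
  expect_equal(d$value[1], 2)
  expect_error(downsample_trace(make_trace(rep(1, 10), fs = 10), 12),
               "below the input rate")
})

test_that("downsampling conserves the mean of fully valid traces", {
  set.seed(11)
  for (i in 1:5) {
    x <- rnorm(300 * 4)                    # length multiple of bin size 25
    tr <- make_trace(x)
    expect_equal(mean(downsample_trace(tr, 12)$value), mean(x),
                 tolerance = 1e-12)
  }
})

test_that("full cleaning chain beats no cleaning on contaminated traces", {
  wins <- vapply(1:20, function(seed) {
    fx <- make_contaminated_trace(seed)
    cleaned <- preprocess_pupil(fx$trace)
    raw12 <- downsample_trace(fx$trace, 12)
    rmse12(cleaned$value, fx$truth12$value) <
      rmse12(raw12$value, fx$truth12$value)
  }, logical(1))
  expect_true(all(wins))
})
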
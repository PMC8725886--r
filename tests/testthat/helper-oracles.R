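# Independent oracles used across the suite. These deliberately take the
# slow, textbook route so they never share code with the implementation.

# Naive per-cell Pearson correlation map (explicit loops).
naive_corr_map <- function(pupil, stack_data, n_min = 2L) {
  d <- dim(stack_data)
  out <- array(NaN, d[2:4])
  for (i in seq_len(d[2])) for (j in seq_len(d[3])) for (c in seq_len(d[4])) {
    x <- stack_data[, i, j, c]
    ok <- is.finite(x) & is.finite(pupil)
    if (sum(ok) < max(2L, n_min)) next
    if (sd(x[ok]) == 0 || sd(pupil[ok]) == 0) next
    out[i, j, c] <- cor(x[ok], pupil[ok])
  }
  out
}

# Brute-force BH step-up: hypothesis j is rejected iff there is a k such
# that at least k of the p-values are <= q*k/m and p_j <= q*k/m. O(m^2).
bh_oracle <- function(p, q) {
  fin <- is.finite(p)
  m <- sum(fin)
  rej <- rep(FALSE, length(p))
  if (m == 0) return(rej)
  for (k in seq_len(m)) {
    thr <- q * k / m
    if (sum(p[fin] <= thr) >= k) rej <- rej | (fin & p <= thr)
  }
  rej
}

# Textbook scalar one-sample t.
scalar_t <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  list(t = mean(x) / (sd(x) / sqrt(n)), df = n - 1,
       p = 2 * pt(-abs(mean(x) / (sd(x) / sqrt(n))), n - 1))
}

# Classical sums-of-squares two-way within-subject ANOVA (uncorrected F).
rm_anova_oracle <- function(y) {
  n <- dim(y)[1]; a <- dim(y)[2]; b <- dim(y)[3]
  m <- mean(y)
  m_s <- apply(y, 1, mean); m_a <- apply(y, 2, mean); m_b <- apply(y, 3, mean)
  m_ab <- apply(y, c(2, 3), mean)
  m_as <- apply(y, c(1, 2), mean)
  m_bs <- apply(y, c(1, 3), mean)
  ss_a <- n * b * sum((m_a - m)^2)
  ss_b <- n * a * sum((m_b - m)^2)
  ss_ab <- n * sum((m_ab - outer(m_a, rep(1, b)) -
                      outer(rep(1, a), m_b) + m)^2)
  ss_as <- b * sum((m_as - outer(m_s, rep(1, a)) -
                      outer(rep(1, n), m_a) + m)^2)
  ss_bs <- a * sum((m_bs - outer(m_s, rep(1, b)) -
                      outer(rep(1, n), m_b) + m)^2)
  ss_s <- a * b * sum((m_s - m)^2)
  ss_tot <- sum((y - m)^2)
  ss_abs <- ss_tot - ss_a - ss_b - ss_ab - ss_s - ss_as - ss_bs
  list(
    F_a = (ss_a / (a - 1)) / (ss_as / ((a - 1) * (n - 1))),
    F_b = (ss_b / (b - 1)) / (ss_bs / ((b - 1) * (n - 1))),
    F_ab = (ss_ab / ((a - 1) * (b - 1))) /
      (ss_abs / ((a - 1) * (b - 1) * (n - 1))))
}

# Contaminated-trace fixture: known smooth ground truth plus blinks with
# partial-closure ramps and isolated spikes, at 300 Hz.
make_contaminated_trace <- function(seed, dur_s = 40, fs = 300) {
  set.seed(seed)
  n <- dur_s * fs
  t <- (0:(n - 1)) / fs
  truth <- 1000 + 40 * sin(2 * pi * 0.15 * t) + 15 * sin(2 * pi * 0.45 * t)
  x <- truth + rnorm(n, 0, 2)
  ramp <- round(0.020 * fs)
  n_blinks <- rpois(1, 15 * dur_s / 60) + 1
  for (i in seq_len(n_blinks)) {
    len <- round(runif(1, 80, 400) * fs / 1000)
    s <- sample(seq(2 * ramp, n - len - 2 * ramp), 1)
    x[(s - ramp):(s - 1)] <- x[(s - ramp):(s - 1)] *
      seq(1, 0.6, length.out = ramp)
    x[(s + len):(s + len + ramp - 1)] <- x[(s + len):(s + len + ramp - 1)] *
      seq(0.6, 1, length.out = ramp)
    x[s:(s + len - 1)] <- NaN
  }
  spikes <- sample(which(is.finite(x)), rpois(1, 3) + 1)
  x[spikes] <- x[spikes] + sample(c(-1, 1), length(spikes), TRUE) * 300
  list(trace = pupil_trace(x, fs, time = t), truth = truth,
       truth12 = downsample_trace(pupil_trace(truth, fs, time = t), 12))
}

# RMSE of a cleaned 12 Hz trace vs the 12 Hz-binned ground truth, over the
# bins where both are finite.
rmse12 <- function(value12, truth12) {
  k <- min(length(value12), length(truth12))
  a <- value12[seq_len(k)]; b <- truth12[seq_len(k)]
  ok <- is.finite(a) & is.finite(b)
  sqrt(mean((a[ok] - b[ok])^2))
}

# Small reduced-scale Exp-1 world shared by recovery tests: scenes at
# 1 px per map cell (80 x 80 screen, 70 x 70 window, factor 1).
small_world_scene <- function(n_frames, seed) {
  scene_sim_config(H = 80L, W = 80L, horizon_row = 40L,
                   n_frames = n_frames, seed = seed)
}

small_world_gaze <- function(n, seed, fs = 300) {
  # geometry scaled by the 10 px/cell factor: 1 px here = 10 px full scale
  simulate_gaze(n, fs = fs, H = 80L, W = 80L, horizon_row = 40L,
                center_offset_px = 0, sd_y_px = 1, sd_x_px = 20,
                dropout_rate = 1, seed = seed)
}

simulate_small_subject <- function(n_frames, seed, pupil_cfg = NULL) {
  seeds <- (seed * 7L + 1:3) %% 2147483647L
  sc <- small_world_scene(n_frames, seeds[1])
  frames <- simulate_scene(sc)
  gaze <- small_world_gaze(round(n_frames / sc$fs * 300), seeds[2])
  if (is.null(pupil_cfg)) pupil_cfg <- pupil_sim_config(kernel_n = 70L)
  pupil_cfg$seed <- seeds[3]
  sim <- simulate_pupil_from_scene(frames, gaze, pupil_cfg,
                                   half = 35L, factor = 1L)
  list(frames = frames, gaze = gaze, pupil = sim$trace, truth = sim$truth)
}

# Bin-mean gaze samples down to the frame rate, truncated to n_frames.
downsample_gaze <- function(v, n_frames, fs = 300, target_fs = 12) {
  out <- downsample_trace(pupil_trace(v, fs), target_fs)$value
  length(out) <- n_frames
  out
}
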
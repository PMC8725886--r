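#' Scene simulation configuration
#'
#' A piecewise-constant outdoor layout: a blue-dominant "sky" region above a
#' horizon row and a red/green-dominant "terrain" region below it, each with
#' AR(1) temporal fluctuations of its mean RGB intensity. This captures the
#' statistics the correlation-map analysis is sensitive to (region-specific
#' channel dominance plus slow temporal fluctuation) without rendering an
#' actual 3-D scene.
#'
#' @param H,W Frame size in pixels.
#' @param horizon_row Row (0-based) of the sky/terrain boundary.
#' @param sky_mean,terrain_mean Mean RGB triples in `[0, 255]`.
#' @param ar_phi AR(1) coefficient of the per-region channel fluctuation
#'   (|phi| < 1; 0.95 at 12 Hz gives a ~1.7 s correlation time, slow enough
#'   for the sluggish pupil to track).
#' @param ar_sd Stationary SD of the fluctuation, intensity levels.
#' @param n_frames Number of frames.
#' @param fs Frame rate in Hz (default 12).
#' @param seed RNG seed.
#' @return List of class `scene_sim_config`.
#' @export
scene_sim_config <- function(H = 1080L, W = 1920L, horizon_row = NULL,
                             sky_mean = c(110, 150, 210),
                             terrain_mean = c(150, 120, 70),
                             ar_phi = 0.95, ar_sd = 8,
                             n_frames = 2000L, fs = 12, seed = 1L) {
  if (is.null(horizon_row)) horizon_row <- H %/% 2L
  stopifnot(H > 0, W > 0, horizon_row > 0, horizon_row < H,
            abs(ar_phi) < 1, ar_sd >= 0, n_frames >= 1, fs > 0)
  structure(list(H = as.integer(H), W = as.integer(W),
                 horizon_row = as.integer(horizon_row),
                 sky_mean = sky_mean, terrain_mean = terrain_mean,
                 ar_phi = ar_phi, ar_sd = ar_sd,
                 n_frames = as.integer(n_frames), fs = fs,
                 seed = seed),
            class = "scene_sim_config")
}

# Stationary AR(1) series of length n: mean mu, marginal sd s, coefficient
# phi (innovation sd scaled accordingly).
ar1_series <- function(n, mu, s, phi) {
  if (s == 0) return(rep(mu, n))
  innov_sd <- s * sqrt(1 - phi^2)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, s)
  e <- stats::rnorm(n - 1, 0, innov_sd)
  for (t in seq_len(n - 1)) x[t + 1] <- phi * x[t] + e[t]
  mu + x
}

#' Simulate a scene frame stack
#'
#' Deterministic given the config seed. The upper region's mean blue level
#' exceeds its mean red level by construction; with `ar_sd = 0` the stack is
#' temporally constant.
#'
#' @param cfg A [scene_sim_config()].
#' @return A [frame_stack()] with integer 8-bit intensities; attribute
#'   `region_series` holds the generating sky/terrain RGB time series.
#' @export
simulate_scene <- function(cfg) {
  stopifnot(inherits(cfg, "scene_sim_config"))
  with_seed(cfg$seed, {
    Tn <- cfg$n_frames
    sky <- sapply(1:3, function(c)
      ar1_series(Tn, cfg$sky_mean[c], cfg$ar_sd, cfg$ar_phi))
    ter <- sapply(1:3, function(c)
      ar1_series(Tn, cfg$terrain_mean[c], cfg$ar_sd, cfg$ar_phi))
    sky <- matrix(pmin(255, pmax(0, round(sky))), Tn, 3)
    ter <- matrix(pmin(255, pmax(0, round(ter))), Tn, 3)
    up <- cfg$horizon_row          # number of sky rows (0-based boundary)
    a <- array(0L, c(Tn, cfg$H, cfg$W, 3L))
    for (c in 1:3) {
      col_block <- cbind(matrix(rep(sky[, c], up), Tn, up),
                         matrix(rep(ter[, c], cfg$H - up), Tn, cfg$H - up))
      a[, , , c] <- array(rep(as.integer(col_block), cfg$W),
                          c(Tn, cfg$H, cfg$W))
    }
    fs <- frame_stack(a, fs = cfg$fs)
    attr(fs, "region_series") <- list(sky = sky, terrain = ter)
    fs
  })
}

#' Simulate a gaze trajectory
#'
#' An Ornstein-Uhlenbeck-style bounded random walk. During level locomotion
#' through an open landscape, vertical gaze concentrates tightly on the
#' horizon while horizontal gaze scans freely, so the vertical component is
#' centered on the horizon row (plus `center_offset_px`) with a small
#' stationary SD and the horizontal component is centered on mid-screen
#' with a much larger SD. Dropout episodes (tracking loss) are inserted as
#' NaN runs at rate `dropout_rate` per minute.
#'
#' @param n Number of samples.
#' @param fs Sampling rate in Hz (eye-tracker rate, e.g. 300).
#' @param H,W Screen size in px.
#' @param horizon_row Horizon row (0-based).
#' @param center_offset_px Vertical offset of the gaze center relative to
#'   the horizon (default 0: gaze rides the horizon line).
#' @param sd_y_px,sd_x_px Stationary SDs of the walk (defaults 10 and
#'   200 px at 1080-px screens, i.e. ~0.2 deg vertical fixation jitter and
#'   ~4 deg horizontal scan).
#' @param phi Per-sample AR coefficient (default 0.995 at 300 Hz:
#'   ~0.7 s time constant, i.e. a few fixations per second).
#' @param dropout_rate Episodes per minute (default 2).
#' @param dropout_ms Mean episode duration (default 600 ms, beyond the
#'   blink range so episodes read as dropouts).
#' @param seed RNG seed.
#' @return Data frame `time`, `x`, `y` (0-based px, NaN during dropouts).
#' @export
simulate_gaze <- function(n, fs = 300, H = 1080L, W = 1920L,
                          horizon_row = H %/% 2L, center_offset_px = 0,
                          sd_y_px = 10, sd_x_px = 200, phi = 0.995,
                          dropout_rate = 2, dropout_ms = 600, seed = 1L) {
  with_seed(seed, {
    cy <- horizon_row + center_offset_px
    y <- ar1_series(n, cy, sd_y_px, phi)
    x <- ar1_series(n, (W - 1) / 2, sd_x_px, phi)
    y <- pmin(H - 1, pmax(0, y))
    x <- pmin(W - 1, pmax(0, x))
    minutes <- n / fs / 60
    k <- stats::rpois(1, dropout_rate * minutes)
    if (k > 0) for (i in seq_len(k)) {
      len <- max(1L, round(stats::rnorm(1, dropout_ms, dropout_ms / 4) *
                             fs / 1000))
      s <- sample.int(max(1L, n - len), 1L)
      x[s:(s + len - 1L)] <- NaN
      y[s:(s + len - 1L)] <- NaN
    }
    data.frame(time = (seq_len(n) - 1) / fs, x = x, y = y)
  })
}

#' Pupil simulation configuration
#'
#' The generative model of the free-viewing pupil trace: a spatially
#' weighted luminance drive from the gaze-contingent window, delayed by
#' `lag_ms`, convolved with a pupil impulse response, inverted (more light,
#' smaller pupil), scaled into device units, and contaminated with Gaussian
#' noise, blinks and spike artifacts.
#'
#' The impulse response is the gamma family
#' `h(t) = t^n * exp(-n t / t_max)` with conventional parameters
#' `n = 10.1`, `t_max = 930` ms, normalized to unit area; `irf = "delta"`
#' replaces it with an impulse so the generative lag is the only delay.
#'
#' @param kernel `n x n x 3` non-negative spatial weight map, normalized to
#'   sum 1; `NULL` selects the default: uniform over the upper-half blue
#'   cells and zero elsewhere.
#' @param kernel_n Cell grid size used when `kernel` is `NULL` (default 70).
#' @param lag_ms Pure generative delay (default 500 ms).
#' @param irf `"gamma"` or `"delta"`.
#' @param irf_n,irf_tmax Gamma IRF parameters (`t_max` in ms).
#' @param noise_sd Gaussian noise SD at the eye-tracker rate, device units.
#' @param gain Device units of pupil change per unit of drive (default
#'   2000; with unit-scale luminance drives this yields fluctuations of a
#'   few tens of a.u. around the baseline, resembling video trackers'
#'   arbitrary pupil-size units).
#' @param baseline Baseline pupil size, device units (default 1000).
#' @param blink_rate Blinks per minute (default 15, a typical resting rate).
#' @param spike_rate Spike artifacts per minute (default 2).
#' @param fs Eye-tracker rate in Hz (default 300).
#' @param seed RNG seed.
#' @return List of class `pupil_sim_config`.
#' @export
pupil_sim_config <- function(kernel = NULL, kernel_n = 70L, lag_ms = 500,
                             irf = c("gamma", "delta"), irf_n = 10.1,
                             irf_tmax = 930, noise_sd = 10, gain = 2000,
                             baseline = 1000, blink_rate = 15,
                             spike_rate = 2, fs = 300, seed = 1L) {
  irf <- match.arg(irf)
  if (is.null(kernel)) {
    kernel <- array(0, c(kernel_n, kernel_n, 3L))
    kernel[seq_len(kernel_n %/% 2L), , 3] <- 1
  }
  stopifnot(all(kernel >= 0), sum(kernel) > 0, irf_tmax > 0, irf_n > 0,
            noise_sd >= 0, blink_rate >= 0, spike_rate >= 0, fs > 0)
  kernel <- kernel / sum(kernel)
  structure(list(kernel = kernel, lag_ms = lag_ms, irf = irf,
                 irf_n = irf_n, irf_tmax = irf_tmax, noise_sd = noise_sd,
                 gain = gain, baseline = baseline, blink_rate = blink_rate,
                 spike_rate = spike_rate, fs = fs, seed = seed),
            class = "pupil_sim_config")
}

# Unit-area gamma IRF sampled at rate fs (truncated at 3 * t_max).
gamma_irf <- function(n, t_max_ms, fs) {
  t <- seq(0, 3 * t_max_ms / 1000, by = 1 / fs)
  h <- t^n * exp(-n * t / (t_max_ms / 1000))
  h / sum(h)
}

#' Simulate a pupil trace from a scene and gaze trajectory
#'
#' Computes the spatially weighted drive from the gaze-contingent window
#' stack (weights renormalized over on-screen cells per frame), upsamples it
#' to the eye-tracker rate, applies the configured delay and impulse
#' response, and produces
#' `pupil = baseline - gain * drive + noise`. Blinks are inserted as missing
#' runs of 50-500 ms flanked by 20 ms partial-closure ramps (a dip toward
#' 60% of the local value) so blink-edge padding is genuinely exercised;
#' spikes are isolated large excursions.
#'
#' @param frames A [frame_stack()] (12 Hz scene).
#' @param gaze Data frame from [simulate_gaze()] at `cfg$fs`.
#' @param cfg A [pupil_sim_config()].
#' @param half,factor Window geometry handed to [gaze_window_stack()];
#'   defaults chosen so the window grid matches `cfg$kernel`.
#' @param gamma [gamma_params()] for the luminance transform.
#' @return List with `trace` (a [pupil_trace()] at `cfg$fs`) and `truth`
#'   (kernel, lag_ms, irf, clean trace at both rates, drive at 12 Hz,
#'   blink and spike sample indices).
#' @export
simulate_pupil_from_scene <- function(frames, gaze, cfg, half = NULL,
                                      factor = 10L,
                                      gamma = gamma_params()) {
  stopifnot(inherits(frames, "frame_stack"),
            inherits(cfg, "pupil_sim_config"))
  kn <- dim(cfg$kernel)[1]
  if (is.null(half)) half <- kn * as.integer(factor) %/% 2L
  stopifnot(2 * half / factor == kn)
  Tn <- dim(frames$frames)[1]
  n <- nrow(gaze)
  # gaze at frame rate: bin means over frame intervals
  gx <- downsample_trace(pupil_trace(gaze$x, cfg$fs, time = gaze$time),
                         frames$fs)$value[seq_len(Tn)]
  gy <- downsample_trace(pupil_trace(gaze$y, cfg$fs, time = gaze$time),
                         frames$fs)$value[seq_len(Tn)]
  stack <- gaze_window_stack(frames, gx, gy, half = half, factor = factor,
                             channel_space = "rgb_lum", gamma = gamma)
  W <- as.vector(cfg$kernel)
  nz <- which(W > 0)
  M <- matrix(stack$data, Tn, length(W))[, nz, drop = FALSE]
  Wn <- W[nz]
  fin <- is.finite(M)
  M0 <- M; M0[!fin] <- 0
  wsum <- fin %*% Wn
  drive12 <- as.vector((M0 %*% Wn) / ifelse(wsum > 0, wsum, NA))
  # fill gaps (missing gaze) so the physiological series stays defined
  if (anyNA(drive12)) {
    ok <- which(is.finite(drive12))
    drive12 <- stats::approx(ok, drive12[ok], xout = seq_len(Tn),
                             rule = 2)$y
  }
  t12 <- frames$timestamps
  thi <- gaze$time[gaze$time <= max(t12) + 1 / frames$fs]
  # zero-order hold: the display shows frame k for the whole frame interval
  drive_hi <- stats::approx(t12, drive12, xout = thi, method = "constant",
                            f = 0, rule = 2)$y
  nh <- length(drive_hi)
  lag_samp <- round(cfg$lag_ms * cfg$fs / 1000)
  delayed <- c(rep(drive_hi[1], lag_samp),
               drive_hi[seq_len(max(0, nh - lag_samp))])
  if (cfg$irf == "gamma") {
    h <- gamma_irf(cfg$irf_n, cfg$irf_tmax, cfg$fs)
    conv <- stats::filter(c(rep(delayed[1], length(h) - 1), delayed),
                          h, sides = 1)
    delayed <- as.numeric(conv)[length(h) - 1 + seq_len(nh)]
  }
  clean <- cfg$baseline - cfg$gain * delayed
  with_seed(cfg$seed, {
    value <- clean + stats::rnorm(nh, 0, cfg$noise_sd)
    minutes <- nh / cfg$fs / 60
    blink_idx <- integer(0)
    nb <- stats::rpois(1, cfg$blink_rate * minutes)
    ramp <- max(1L, round(0.020 * cfg$fs))
    if (nb > 0) for (i in seq_len(nb)) {
      len <- round(stats::runif(1, 60, 450) * cfg$fs / 1000)
      s <- sample.int(max(1L, nh - len - 2L * ramp), 1L) + ramp
      pre <- (s - ramp):(s - 1L)
      post <- (s + len):(s + len + ramp - 1L)
      value[pre] <- value[pre] * seq(1, 0.6, length.out = ramp)
      value[post] <- value[post] * seq(0.6, 1, length.out = ramp)
      value[s:(s + len - 1L)] <- NaN
      blink_idx <- c(blink_idx, s:(s + len - 1L))
    }
    spike_idx <- integer(0)
    ns <- stats::rpois(1, cfg$spike_rate * minutes)
    if (ns > 0) {
      spike_idx <- sample.int(nh, ns)
      value[spike_idx] <- value[spike_idx] +
        sample(c(-1, 1), ns, TRUE) * 8 * max(cfg$noise_sd, 1) *
          stats::runif(ns, 1, 2)
    }
    trace <- pupil_trace(value, cfg$fs, time = thi)
    truth <- list(kernel = cfg$kernel, lag_ms = cfg$lag_ms,
                  irf = cfg$irf, drive12 = drive12,
                  clean_hi = clean,
                  clean12 = downsample_trace(
                    pupil_trace(clean, cfg$fs, time = thi), frames$fs),
                  blink_idx = blink_idx, spike_idx = spike_idx)
    list(trace = trace, truth = truth)
  })
}

#' Build the canonical flashed-stimulus trial design
#'
#' Full crossing of colors and locations, replicated and shuffled. The
#' canonical design (3 colors x 4 locations x 5 reps) has 12 conditions and
#' 60 trials.
#'
#' @param colors,locations Condition levels.
#' @param reps Replications per condition (default 5).
#' @param seed Shuffle seed (`NULL` keeps systematic order).
#' @return Data frame `trial`, `color`, `location`.
#' @export
build_exp2_design <- function(colors = .ps_colors,
                              locations = .ps_locations,
                              reps = 5L, seed = NULL) {
  stopifnot(reps >= 1L)
  g <- expand.grid(color = colors, location = locations,
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  ord <- if (is.null(seed)) seq_len(nrow(g))
         else with_seed(seed, sample.int(nrow(g)))
  g <- g[ord, c("color", "location")]
  rownames(g) <- NULL
  cbind(trial = seq_len(nrow(g)), g)
}

#' Flashed-stimulus experiment configuration
#'
#' Default condition amplitudes are the group means of the reference
#' experiment: red -37.7%, green -37.2%, blue -44.3% peak constriction,
#' with an extra -4% for blue-top (the blue-sky effect the design is built
#' to detect). Between-subject SD 3%, within-subject (trial) SD 3%,
#' sample noise 5 a.u. on a ~920 a.u. baseline.
#'
#' @param amplitude `3 x 4` matrix (colors x locations) of mean PLRmin
#'   percentages; `NULL` selects the defaults above.
#' @param blue_top_extra Additional amplitude for the blue-top cell applied
#'   when `amplitude` is `NULL` (default -4).
#' @param between_sd,within_sd Between-subject and per-trial amplitude SDs
#'   (percent).
#' @param sample_noise_sd Additive sample noise SD, device units.
#' @param blink_prob Probability that a trial contains a blink in
#'   `(0, 1500]` ms.
#' @param n_subjects Number of subjects (default 15).
#' @param reps Trials per condition (default 5).
#' @param baseline_mean,baseline_sd Between-subject baseline distribution,
#'   device units.
#' @param fs Sampling rate in Hz (default 1000).
#' @param window Epoch window in ms (default `c(-500, 2500)`).
#' @param irf_n,irf_tmax Gamma waveform parameters (peak at `t_max`).
#' @param seed RNG seed.
#' @return List of class `exp2_sim_config`.
#' @export
exp2_sim_config <- function(amplitude = NULL, blue_top_extra = -4,
                            between_sd = 3, within_sd = 3,
                            sample_noise_sd = 5, blink_prob = 0.15,
                            n_subjects = 15L, reps = 5L,
                            baseline_mean = 920, baseline_sd = 250,
                            fs = 1000, window = c(-500, 2500),
                            irf_n = 10.1, irf_tmax = 930, seed = 1L) {
  if (is.null(amplitude)) {
    amplitude <- matrix(rep(c(-37.7, -37.2, -44.3), 4), 3, 4,
                        dimnames = list(.ps_colors, .ps_locations))
    amplitude["blue", "top"] <- amplitude["blue", "top"] + blue_top_extra
  }
  stopifnot(nrow(amplitude) == 3L, ncol(amplitude) == 4L,
            between_sd >= 0, within_sd >= 0, sample_noise_sd >= 0,
            blink_prob >= 0, blink_prob <= 1, n_subjects >= 1, reps >= 1,
            fs > 0, window[1] <= -500, window[2] >= 2000)
  if (is.null(dimnames(amplitude)))
    dimnames(amplitude) <- list(.ps_colors, .ps_locations)
  structure(list(amplitude = amplitude, between_sd = between_sd,
                 within_sd = within_sd, sample_noise_sd = sample_noise_sd,
                 blink_prob = blink_prob, n_subjects = as.integer(n_subjects),
                 reps = as.integer(reps), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, fs = fs, window = window,
                 irf_n = irf_n, irf_tmax = irf_tmax, seed = seed),
            class = "exp2_sim_config")
}

#' Simulate flashed-stimulus trial epochs
#'
#' Each trial's epoch is
#' `x(t) = B * (1 + A_trial/100 * h(t)) + noise`, where `h` is the gamma
#' waveform normalized to peak 1 at `t_max` (so the noiseless PLRmin equals
#' `A_trial` exactly) and
#' `A_trial ~ Normal(A[color, location] + subject_offset, within_sd)`.
#' Blinks are inserted with probability `blink_prob` as 100-300 ms missing
#' runs starting in `(0, 1500]` ms.
#'
#' @param cfg An [exp2_sim_config()].
#' @return List with `subjects` (list of [epoch_set()]) and `truth`
#'   (amplitude table, per-subject offsets and baselines, design).
#' @export
simulate_exp2 <- function(cfg) {
  stopifnot(inherits(cfg, "exp2_sim_config"))
  with_seed(cfg$seed, {
    time <- seq(cfg$window[1], cfg$window[2], by = 1000 / cfg$fs) / 1000
    post <- pmax(time, 0)
    h <- (post / (cfg$irf_tmax / 1000))^cfg$irf_n *
      exp(cfg$irf_n * (1 - post / (cfg$irf_tmax / 1000)))
    h[time <= 0] <- 0
    subjects <- vector("list", cfg$n_subjects)
    offsets <- stats::rnorm(cfg$n_subjects, 0, cfg$between_sd)
    baselines <- pmax(200, stats::rnorm(cfg$n_subjects, cfg$baseline_mean,
                                        cfg$baseline_sd))
    for (s in seq_len(cfg$n_subjects)) {
      des <- build_exp2_design(reps = cfg$reps,
                               seed = (cfg$seed * 131 + s) %% 2147483647)
      nt <- nrow(des)
      A <- cfg$amplitude[cbind(des$color, des$location)] + offsets[s] +
        stats::rnorm(nt, 0, cfg$within_sd)
      base <- baselines[s]
      smp <- base * (1 + outer(A / 100, h)) +
        matrix(stats::rnorm(nt * length(time), 0, cfg$sample_noise_sd),
               nt, length(time))
      blink <- stats::runif(nt) < cfg$blink_prob
      for (i in which(blink)) {
        onset <- stats::runif(1, 0.001, 1.4)
        len <- round(stats::runif(1, 100, 300) * cfg$fs / 1000)
        j0 <- which.min(abs(time - onset))
        smp[i, j0:min(length(time), j0 + len - 1L)] <- NaN
      }
      subjects[[s]] <- epoch_set(time, smp, des$color, des$location,
                                 fs = cfg$fs)
    }
    list(subjects = subjects,
         truth = list(amplitude = cfg$amplitude, offsets = offsets,
                      baselines = baselines))
  })
}
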
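#' Convert a lag in milliseconds to whole frames
#'
#' @param lag_ms Lag in milliseconds.
#' @param fs Frame rate in Hz (default 12).
#' @return Integer number of frames, `round(lag_ms * fs / 1000)`.
#' @export
lag_ms_to_frames <- function(lag_ms, fs = 12) {
  as.integer(round(lag_ms * fs / 1000))
}

#' Estimate the pupil lag by cross-correlation
#'
#' Because the pupillary response is sluggish, pupil size trails the
#' luminance it reacts to. The lag is estimated by evaluating the Pearson
#' correlation between `drive(t)` and `pupil(t + tau)` for non-negative
#' integer frame offsets and taking the offset at the peak. Since luminance
#' and pupil size are inversely related, the default peak is the most
#' negative correlation; `mode = "abs"` uses the largest magnitude instead.
#'
#' @param pupil,drive Numeric series at the frame rate (`NaN` allowed).
#' @param fs Sampling rate in Hz (default 12).
#' @param max_lag_ms Largest offset searched (default 2000 ms).
#' @param mode `"neg"` (most negative r) or `"abs"`.
#' @param min_pairs Minimum complete pairs required at every candidate lag
#'   (default 50).
#' @return List of class `lag_estimate`: `lag_ms`, `lag_frames`,
#'   `r_at_peak`, `low_confidence` (`TRUE` when `|r| < 0.1`).
#' @export
estimate_lag <- function(pupil, drive, fs = 12, max_lag_ms = 2000,
                         mode = c("neg", "abs"), min_pairs = 50L) {
  mode <- match.arg(mode)
  n <- length(pupil)
  stopifnot(length(drive) == n)
  if (stats::sd(pupil, na.rm = TRUE) == 0 ||
      stats::sd(drive, na.rm = TRUE) == 0)
    stop("constant series: lag is undefined")
  max_lag <- lag_ms_to_frames(max_lag_ms, fs)
  if (max_lag >= n) stop("max_lag_ms exceeds series duration")
  taus <- 0:max_lag
  rs <- vapply(taus, function(tau) {
    a <- drive[seq_len(n - tau)]
    b <- pupil[seq_len(n - tau) + tau]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < min_pairs)
      stop("fewer than ", min_pairs, " complete pairs at lag ", tau)
    if (stats::sd(a[ok]) == 0 || stats::sd(b[ok]) == 0) return(NA_real_)
    stats::cor(a[ok], b[ok])
  }, 0)
  pick <- if (mode == "neg") which.min(rs) else which.max(abs(rs))
  tau <- taus[pick]
  structure(list(lag_ms = tau * 1000 / fs, lag_frames = tau,
                 r_at_peak = rs[pick],
                 low_confidence = abs(rs[pick]) < 0.1,
                 r_by_lag = stats::setNames(rs, taus)),
            class = "lag_estimate")
}

#' Shift the pupil series to undo its lag
#'
#' Pairs `pupil(t + lag)` with `scene(t)`: returns the pupil series with the
#' first `lag_frames` samples dropped; the caller drops the last
#' `lag_frames` scene frames so the lengths match.
#'
#' @param pupil Numeric series.
#' @param lag_frames Non-negative integer lag in frames.
#' @return Numeric vector of length `length(pupil) - lag_frames`.
#' @export
shift_pupil <- function(pupil, lag_frames) {
  stopifnot(lag_frames >= 0)
  n <- length(pupil)
  if (lag_frames >= n) stop("lag_frames must be below the series length")
  if (lag_frames == 0) return(pupil)
  pupil[(lag_frames + 1L):n]
}

#' Mean channel drive over the gaze window
#'
#' Per-frame, per-channel mean over the non-`NaN` window cells; the default
#' drive used for lag estimation.
#'
#' @param windows A `gaze_window_stack`.
#' @return `T x 3` matrix.
#' @export
window_drive <- function(windows) {
  a <- windows$data
  d <- dim(a)
  m <- matrix(NaN, d[1], d[4])
  for (c in seq_len(d[4])) {
    x <- matrix(a[, , , c], d[1], d[2] * d[3])
    cnt <- rowSums(is.finite(x))
    x[!is.finite(x)] <- 0
    m[, c] <- ifelse(cnt > 0, rowSums(x) / cnt, NaN)
  }
  colnames(m) <- c("ch1", "ch2", "ch3")
  m
}

#' Pixel-wise Pearson correlation map
#'
#' For every window cell and channel, the Pearson correlation over the time
#' points where both the (lag-aligned) pupil and that cell are finite
#' (pairwise-complete). Cells with fewer than `n_min` pairs or zero variance
#' are `NaN`.
#'
#' @param pupil_aligned Numeric series, same length as the window stack.
#' @param windows A `gaze_window_stack` (its first `length(pupil_aligned)`
#'   frames are used; pass a pre-truncated stack for lag alignment).
#' @param n_min Minimum paired-sample count per cell; default
#'   `max(100, 0.05 * T)`, guarding against spurious r at high-`NaN` edge
#'   cells.
#' @param lag_frames Lag used for alignment, recorded as metadata.
#' @return Object of class `correlation_map`: list with `r`
#'   (`n x n x C`), `n_eff` (`n x n x C`), `lag_frames`, `channel_space`.
#' @export
pixel_correlation_map <- function(pupil_aligned, windows, n_min = NULL,
                                  lag_frames = NA_integer_) {
  a <- windows$data
  d <- dim(a)
  Tn <- length(pupil_aligned)
  if (Tn != d[1]) stop("pupil length must equal the number of frames")
  if (is.null(n_min)) n_min <- max(100, ceiling(0.05 * Tn))
  M <- matrix(a, Tn, d[2] * d[3] * d[4])
  pupil_ok <- is.finite(pupil_aligned)
  # pairwise-complete Pearson r via masked cross-products; the pupil is
  # centered on its overall mean so the update formulas stay numerically
  # benign (channel values are O(1) already)
  fin <- is.finite(M)
  p0 <- ifelse(pupil_ok, pupil_aligned - mean(pupil_aligned[pupil_ok]), 0)
  M[!fin] <- 0
  okv <- as.numeric(pupil_ok)
  A <- crossprod(fin, cbind(okv, p0, p0 * p0))
  n_eff <- A[, 1]; sy <- A[, 2]; syy <- A[, 3]
  M2 <- M * okv
  sx <- colSums(M2)
  sxx <- colSums(M2 * M)
  sxy <- as.vector(crossprod(M, p0))
  vx <- sxx - sx^2 / pmax(n_eff, 1)
  vy <- syy - sy^2 / pmax(n_eff, 1)
  r <- (sxy - sx * sy / n_eff) / sqrt(pmax(vx, 0) * pmax(vy, 0))
  r[n_eff < pmax(2, n_min) | vx <= 0 | vy <= 0] <- NaN
  r[!is.finite(r)] <- NaN
  r <- pmin(1, pmax(-1, r))
  if (all(!is.finite(r))) stop("all cells NaN: no usable pixels")
  structure(list(r = array(r, d[2:4]),
                 n_eff = array(n_eff, d[2:4]),
                 lag_frames = lag_frames,
                 channel_space = windows$channel_space),
            class = "correlation_map")
}

#' Correlation between two channels' cell series
#'
#' Per-cell Pearson correlation between the time series of two channels of
#' the same window stack (pairwise-complete), needed by the
#' dependent-correlation comparison, which must account for how strongly
#' the two channels co-vary.
#'
#' @param windows A `gaze_window_stack`.
#' @param ch_a,ch_b Channel indices in 1..3.
#' @param n_min Minimum pairs per cell (default as in
#'   [pixel_correlation_map()]).
#' @return `n x n` matrix of correlations (NaN where undefined).
#' @export
channel_channel_map <- function(windows, ch_a, ch_b, n_min = NULL) {
  a <- windows$data
  d <- dim(a)
  Tn <- d[1]
  if (is.null(n_min)) n_min <- max(100, ceiling(0.05 * Tn))
  A <- matrix(a[, , , ch_a], Tn, d[2] * d[3])
  B <- matrix(a[, , , ch_b], Tn, d[2] * d[3])
  ok <- is.finite(A) & is.finite(B)
  A[!ok] <- NA; B[!ok] <- NA
  n <- colSums(ok)
  sa <- colSums(A, na.rm = TRUE); sb <- colSums(B, na.rm = TRUE)
  saa <- colSums(A * A, na.rm = TRUE); sbb <- colSums(B * B, na.rm = TRUE)
  sab <- colSums(A * B, na.rm = TRUE)
  num <- sab - sa * sb / n
  den <- sqrt(pmax(saa - sa^2 / n, 0) * pmax(sbb - sb^2 / n, 0))
  r <- ifelse(n >= pmax(2, n_min) & den > 0, num / den, NaN)
  matrix(pmin(1, pmax(-1, r)), d[2], d[3])
}
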
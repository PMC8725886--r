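#' Construct a pupil trace
#'
#' A regularly sampled pupil-size series in device units with a validity
#' mask. `NaN` values and `valid = FALSE` are kept consistent: a sample is
#' valid iff its value is finite and flagged valid.
#'
#' @param value Numeric vector of pupil sizes (device units).
#' @param fs Sampling rate in Hz.
#' @param time Sample times in seconds; defaults to `(0:(n-1))/fs`.
#' @param valid Logical validity mask; defaults to `is.finite(value)`.
#' @param unit Device unit string carried as metadata.
#' @return Object of class `pupil_trace`: list with `time`, `value`, `valid`,
#'   `fs`, `unit`.
#' @export
pupil_trace <- function(value, fs, time = NULL, valid = NULL, unit = "a.u.") {
  stopifnot(is.numeric(value), fs > 0)
  n <- length(value)
  if (is.null(time)) time <- (seq_len(n) - 1) / fs
  if (is.null(valid)) valid <- is.finite(value)
  stopifnot(length(time) == n, length(valid) == n)
  valid <- valid & is.finite(value)
  value[!valid] <- NaN
  structure(list(time = time, value = value, valid = valid,
                 fs = fs, unit = unit),
            class = "pupil_trace")
}

#' @export
print.pupil_trace <- function(x, ...) {
  cat(sprintf("<pupil_trace> %d samples @ %.5g Hz, %.1f%% missing (%s)\n",
              length(x$value), x$fs, 100 * mean(!x$valid), x$unit))
  invisible(x)
}

#' Preprocessing parameters
#'
#' Defaults follow standard practice for video-based pupillometry: two
#' velocity-outlier passes at 2.0 then 2.5 SD, blinks defined as 50-500 ms
#' dropouts, up to 50 ms of padding around each blink, and an 11 ms Hanning
#' window for blink-edge velocity smoothing.
#'
#' @param k1,k2 SD multipliers for the first and second velocity-outlier
#'   pass (`k2 > k1 > 0`).
#' @param blink_pad_ms Maximum extension of each blink edge, ms.
#' @param hann_ms Width of the Hanning smoothing window, ms.
#' @param blink_min_ms,blink_max_ms Duration bounds of a blink, ms; longer
#'   gaps are dropouts.
#' @param target_fs Analysis sampling rate after downsampling, Hz.
#' @param edge_vel_mult Blink-edge velocity threshold as a multiple of the
#'   median absolute deviation of the smoothed velocity.
#' @return A list of class `preprocess_params`.
#' @export
preprocess_params <- function(k1 = 2.0, k2 = 2.5, blink_pad_ms = 50,
                              hann_ms = 11, blink_min_ms = 50,
                              blink_max_ms = 500, target_fs = 12,
                              edge_vel_mult = 3) {
  stopifnot(k2 > k1, k1 > 0, blink_pad_ms > 0, hann_ms > 0,
            blink_min_ms > 0, blink_max_ms > blink_min_ms, target_fs > 0,
            edge_vel_mult > 0)
  structure(list(k1 = k1, k2 = k2, blink_pad_ms = blink_pad_ms,
                 hann_ms = hann_ms, blink_min_ms = blink_min_ms,
                 blink_max_ms = blink_max_ms, target_fs = target_fs,
                 edge_vel_mult = edge_vel_mult),
            class = "preprocess_params")
}

#' Select the eye with less missing data
#'
#' Averaging the two eyes can create discontinuities when data drop out from
#' one eye only, so the eye with the smaller invalid fraction is analyzed.
#' Ties go to the left eye.
#'
#' @param left,right `pupil_trace` objects of equal length and rate.
#' @return The selected `pupil_trace`, with attribute `eye` (`"left"` or
#'   `"right"`).
#' @export
select_eye <- function(left, right) {
  stopifnot(inherits(left, "pupil_trace"), inherits(right, "pupil_trace"))
  if (length(left$value) != length(right$value) || left$fs != right$fs)
    stop("left/right traces must have equal length and sampling rate")
  fl <- missing_fraction(left); fr <- missing_fraction(right)
  if (fl >= 1 && fr >= 1) stop("both eyes are fully missing")
  out <- if (fr < fl) right else left
  attr(out, "eye") <- if (fr < fl) "right" else "left"
  out
}

#' Fraction of invalid samples
#' @param trace A `pupil_trace`.
#' @return Fraction in `[0, 1]`.
#' @export
missing_fraction <- function(trace) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (!length(trace$value)) stop("empty trace")
  mean(!trace$valid)
}

# First-difference velocity; element i is the velocity *into* sample i
# (NA at i = 1 and wherever either endpoint is invalid).
trace_velocity <- function(value, fs) {
  c(NA_real_, diff(value) * fs)
}

#' Remove velocity outliers (two-pass)
#'
#' Tracker artifacts appear as physiologically unrealistic jumps. Pass 1
#' flags samples whose velocity deviates more than `k1` SD from the mean
#' velocity; pass 2 recomputes mean/SD on the survivors and flags beyond
#' `k2` SD. An offending velocity flags its later sample. Flagged samples
#' are set to `NaN` and then filled by linear interpolation between the
#' nearest valid neighbours.
#'
#' @param trace A `pupil_trace`.
#' @param params [preprocess_params()].
#' @return The cleaned `pupil_trace`; attribute `n_flagged` gives the count
#'   per pass.
#' @export
remove_velocity_outliers <- function(trace, params = preprocess_params()) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$value
  if (sum(is.finite(x)) < 3L)
    stop("need at least 3 valid samples for velocity-outlier removal")
  v <- trace_velocity(x, trace$fs)
  ok <- is.finite(v)
  if (!any(ok) || stats::sd(v[ok]) == 0) {
    warning("zero velocity variance; trace returned unchanged")
    attr(trace, "n_flagged") <- c(0L, 0L)
    return(trace)
  }
  m1 <- mean(v[ok]); s1 <- stats::sd(v[ok])
  flag1 <- ok & abs(v - m1) > params$k1 * s1
  surv <- ok & !flag1
  if (sum(surv) >= 2L && stats::sd(v[surv]) > 0) {
    m2 <- mean(v[surv]); s2 <- stats::sd(v[surv])
    flag2 <- surv & abs(v - m2) > params$k2 * s2
  } else flag2 <- rep(FALSE, length(v))
  flagged <- flag1 | flag2
  x[flagged] <- NaN
  fill <- flagged  # only repair what this step removed
  if (any(fill)) {
    good <- which(is.finite(x))
    x[fill] <- stats::approx(trace$time[good], x[good],
                             xout = trace$time[fill], rule = 2)$y
  }
  out <- pupil_trace(x, trace$fs, time = trace$time,
                     valid = trace$valid | fill, unit = trace$unit)
  out$valid <- out$valid & is.finite(out$value)
  attr(out, "n_flagged") <- c(sum(flag1), sum(flag2))
  out
}

#' Detect blinks as bounded runs of missing data
#'
#' Maximal runs of contiguous invalid samples whose duration lies within
#' `[blink_min_ms, blink_max_ms]` are blinks; longer runs are classified as
#' signal dropouts and left alone.
#'
#' @param trace A `pupil_trace`.
#' @param params [preprocess_params()].
#' @return Data frame with columns `start`, `end` (1-based inclusive sample
#'   indices) and `duration_ms`; zero rows when there is no blink.
#' @export
detect_blinks <- function(trace, params = preprocess_params()) {
  stopifnot(inherits(trace, "pupil_trace"))
  r <- rle(!trace$valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  dur <- r$lengths / trace$fs * 1000
  keep <- r$values & dur >= params$blink_min_ms & dur <= params$blink_max_ms
  data.frame(start = starts[keep], end = ends[keep],
             duration_ms = dur[keep])
}

# Hanning (raised cosine) smoothing with the nearest odd sample count to
# width_ms; NA-tolerant via renormalized weights.
hann_smooth <- function(x, fs, width_ms) {
  n <- max(3L, round(width_ms * fs / 1000))
  if (n %% 2L == 0L) n <- n + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))
  w <- w / sum(w)
  xx <- x; xx[!is.finite(xx)] <- 0
  mask <- as.numeric(is.finite(x))
  pad <- (n - 1L) / 2L
  num <- stats::filter(c(rep(0, pad), xx, rep(0, pad)), w, sides = 2)
  den <- stats::filter(c(rep(0, pad), mask, rep(0, pad)), w, sides = 2)
  out <- as.numeric(num / den)[(pad + 1L):(pad + length(x))]
  out[!is.finite(out)] <- NA_real_
  out
}

#' Repair blinks by padded linear interpolation
#'
#' Partial eyelid closure distorts samples flanking each missing run, so the
#' trace is smoothed with a Hanning window (nearest odd sample count to
#' `hann_ms`), each blink onset is extended backward and its offset forward
#' (each by up to `blink_pad_ms`) to the nearest sample where the smoothed
#' |velocity| falls below a robust threshold, and the extended interval is
#' linearly interpolated between its boundary samples. Blinks truncated at
#' the trace edge are filled with the nearest valid value.
#'
#' @param trace A `pupil_trace`.
#' @param blinks Output of [detect_blinks()] on the same trace.
#' @param params [preprocess_params()]; the edge threshold is
#'   `edge_vel_mult` times the MAD of the smoothed velocity.
#' @return The repaired `pupil_trace` (repaired samples become valid);
#'   attribute `repaired` holds the padded intervals used.
#' @export
repair_blinks <- function(trace, blinks, params = preprocess_params()) {
  stopifnot(inherits(trace, "pupil_trace"))
  x <- trace$value
  n <- length(x)
  if (!nrow(blinks)) {
    attr(trace, "repaired") <- blinks
    return(trace)
  }
  sm <- hann_smooth(x, trace$fs, params$hann_ms)
  v <- trace_velocity(sm, trace$fs)
  thr <- params$edge_vel_mult * stats::mad(v, na.rm = TRUE)
  pad <- max(1L, round(params$blink_pad_ms * trace$fs / 1000))
  iv <- blinks
  for (i in seq_len(nrow(iv))) {
    s <- iv$start[i]
    for (k in seq_len(pad)) {          # extend onset backward
      j <- iv$start[i] - k
      if (j < 1L) break
      s <- j
      if (is.finite(v[j]) && abs(v[j]) < thr) break
    }
    e <- iv$end[i]
    for (k in seq_len(pad)) {          # extend offset forward
      j <- iv$end[i] + k
      if (j > n) break
      e <- j
      if (is.finite(v[j + 1L]) && abs(v[j + 1L]) < thr) break
    }
    iv$start[i] <- s; iv$end[i] <- e
  }
  # blinks whose padded spans overlap or abut (partial reopening mid-blink)
  # are repaired as one interval, so neither interpolates from the
  # closure-contaminated sliver between them
  if (nrow(iv) > 1L) {
    keep <- rep(TRUE, nrow(iv))
    for (i in 2:nrow(iv)) {
      j <- max(which(keep[seq_len(i - 1L)]))
      if (iv$start[i] <= iv$end[j] + 1L) {
        iv$end[j] <- max(iv$end[j], iv$end[i])
        keep[i] <- FALSE
      }
    }
    iv <- iv[keep, , drop = FALSE]
  }
  for (i in seq_len(nrow(iv))) {
    s <- iv$start[i]; e <- iv$end[i]
    lo <- s - 1L; hi <- e + 1L
    left_ok <- lo >= 1L && is.finite(x[lo])
    right_ok <- hi <= n && is.finite(x[hi])
    idx <- s:e
    if (left_ok && right_ok) {
      x[idx] <- x[lo] + (x[hi] - x[lo]) * (idx - lo) / (hi - lo)
    } else if (left_ok) {
      x[idx] <- x[lo]
    } else if (right_ok) {
      x[idx] <- x[hi]
    }  # both edges missing: leave as-is (pure dropout at both ends)
  }
  out <- pupil_trace(x, trace$fs, time = trace$time,
                     valid = is.finite(x), unit = trace$unit)
  attr(out, "repaired") <- iv
  out
}

#' Downsample a trace by bin averaging
#'
#' Output sample `k` (0-based) is the mean of the valid input samples whose
#' time falls in `[k/target_fs, (k+1)/target_fs)` relative to the first
#' sample; an all-invalid bin yields `NaN`. Bin means act as a crude
#' anti-aliasing filter, unlike decimation.
#'
#' @param trace A `pupil_trace`.
#' @param target_fs Target rate in Hz, strictly less than `trace$fs`.
#' @return A `pupil_trace` at `target_fs`.
#' @export
downsample_trace <- function(trace, target_fs) {
  stopifnot(inherits(trace, "pupil_trace"))
  if (target_fs >= trace$fs) stop("target_fs must be below the input rate")
  rel <- trace$time - trace$time[1]
  bin <- as.integer(floor(rel * target_fs + 1e-9))
  nb <- max(bin) + 1L
  ok <- trace$valid
  sums <- rowsum(ifelse(ok, trace$value, 0), bin)
  cnts <- rowsum(as.numeric(ok), bin)
  full <- numeric(nb); fully <- numeric(nb)
  idx <- as.integer(rownames(sums)) + 1L
  full[idx] <- sums; fully[idx] <- cnts
  val <- ifelse(fully > 0, full / fully, NaN)
  pupil_trace(val, target_fs,
              time = trace$time[1] + (seq_len(nb) - 1) / target_fs,
              unit = trace$unit)
}

#' Full pupil preprocessing chain
#'
#' Eye selection (when two traces are given), two-pass velocity-outlier
#' removal, blink detection and padded repair, and bin-mean downsampling to
#' the analysis rate.
#'
#' @param left A `pupil_trace` (or the only trace).
#' @param right Optional second `pupil_trace`.
#' @param params [preprocess_params()].
#' @return A `pupil_trace` at `params$target_fs`; attribute `qc` records the
#'   selected eye, pre-repair missing fraction and blink count.
#' @export
preprocess_pupil <- function(left, right = NULL,
                             params = preprocess_params()) {
  tr <- if (is.null(right)) left else select_eye(left, right)
  eye <- attr(tr, "eye")
  raw_missing <- missing_fraction(tr)
  tr2 <- remove_velocity_outliers(tr, params)
  blinks <- detect_blinks(tr2, params)
  tr3 <- repair_blinks(tr2, blinks, params)
  out <- downsample_trace(tr3, params$target_fs)
  attr(out, "qc") <- list(eye = eye, missing_fraction = raw_missing,
                          n_blinks = nrow(blinks))
  out
}
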
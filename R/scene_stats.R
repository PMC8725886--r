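#' Display gamma parameters
#'
#' Per-channel exponents of the display's code-to-luminance transfer
#' function `L = scale * (v/255)^gamma`. The defaults are the fitted
#' exponents of the experimental display (red 2.24, green 2.23, blue 2.22)
#' with unit peak scales; Pearson correlations are invariant to the positive
#' scale, so `scale = 1` is used unless measured peak luminances (cd/m^2)
#' are available.
#'
#' @param gamma_r,gamma_g,gamma_b Channel exponents (> 0).
#' @param scale_r,scale_g,scale_b Peak luminance per channel (> 0).
#' @return A list of class `gamma_params`.
#' @export
gamma_params <- function(gamma_r = 2.24, gamma_g = 2.23, gamma_b = 2.22,
                         scale_r = 1, scale_g = 1, scale_b = 1) {
  g <- c(gamma_r, gamma_g, gamma_b); s <- c(scale_r, scale_g, scale_b)
  stopifnot(all(g > 0), all(s > 0))
  structure(list(gamma = g, scale = s), class = "gamma_params")
}

#' Fit a display gamma from photometer measurements
#'
#' Least-squares fit of `L = scale * (v/255)^gamma` to luminance
#' measurements taken while stepping one channel through its 8-bit codes.
#' `scale` is profiled out analytically; `gamma` is found by 1-D
#' optimization.
#'
#' @param levels Integer intensity codes in `[0, 255]`; at least 4 distinct
#'   levels including a high one (max >= 192) are required.
#' @param measured Luminances in cd/m^2 (>= 0).
#' @return List with `gamma`, `scale` and `resid_norm` (residual 2-norm).
#' @export
fit_gamma <- function(levels, measured) {
  stopifnot(length(levels) == length(measured))
  if (length(unique(levels)) < 4L)
    stop("need at least 4 distinct intensity levels")
  if (max(levels) < 192) stop("need a high intensity level (max >= 192)")
  if (any(measured < 0)) stop("negative luminance measurement")
  if (all(measured == 0)) stop("all-zero luminance measurements")
  o <- order(levels)
  dl <- diff(measured[o])
  if (any(dl < -0.02 * diff(range(measured))))
    warning("luminance series is non-monotone beyond tolerance")
  x <- levels / 255
  rss <- function(g) {
    xg <- x^g
    sc <- sum(measured * xg) / sum(xg * xg)
    sum((measured - sc * xg)^2)
  }
  g <- stats::optimize(rss, c(0.2, 8))$minimum
  xg <- x^g
  sc <- sum(measured * xg) / sum(xg * xg)
  list(gamma = g, scale = sc, resid_norm = sqrt(rss(g)))
}

#' Transform 8-bit RGB frames to per-channel luminance
#'
#' Applies `L_c = scale_c * (v/255)^gamma_c` pointwise; strictly monotone in
#' `v` for each channel.
#'
#' @param frames A [frame_stack()] or a numeric array whose last dimension
#'   has length 3 and values in `[0, 255]`.
#' @param params [gamma_params()].
#' @return Array of the same shape in luminance units (`[0, scale]`), with
#'   attribute `channel_space = "rgb_lum"`.
#' @export
gamma_transform <- function(frames, params = gamma_params()) {
  a <- if (inherits(frames, "frame_stack")) frames$frames else frames
  d <- dim(a)
  stopifnot(d[length(d)] == 3L)
  m <- matrix(a, ncol = 3L)  # column-major: channel is the slowest dim
  for (c in 1:3)
    m[, c] <- params$scale[c] * (m[, c] / 255)^params$gamma[c]
  out <- array(m, d)
  attr(out, "channel_space") <- "rgb_lum"
  out
}

#' Convert 8-bit RGB frames to CIELAB
#'
#' Assumes sRGB primaries and D65 white. The CIE convention is kept:
#' positive a* is red, negative green; positive b* yellow, negative blue.
#' Displays that describe the a* axis with the opposite polarity can be
#' matched by negating a* downstream; the returned attribute
#' `lab_polarity = c(a = 1, b = 1)` documents the orientation in force.
#'
#' @param frames A [frame_stack()] or numeric array with trailing channel
#'   dimension of length 3, values in `[0, 255]`.
#' @return Array of the same shape with channels L* (0-100), a*, b*;
#'   attributes `channel_space = "cielab"` and `lab_polarity`.
#' @export
rgb_to_cielab <- function(frames) {
  a <- if (inherits(frames, "frame_stack")) frames$frames else frames
  d <- dim(a)
  stopifnot(d[length(d)] == 3L)
  m <- matrix(a, ncol = 3L)  # column-major: channel is the slowest dim
  ok <- stats::complete.cases(m)
  lab <- matrix(NA_real_, nrow(m), 3L)
  if (any(ok))
    lab[ok, ] <- farver::convert_colour(m[ok, , drop = FALSE],
                                        from = "rgb", to = "lab")
  out <- array(lab, d)
  attr(out, "channel_space") <- "cielab"
  attr(out, "lab_polarity") <- c(a = 1, b = 1)
  out
}

#' Extract a square gaze-centered window from one frame
#'
#' The window covers rows `gy - half .. gy + half - 1` and columns
#' `gx - half .. gx + half - 1` in 0-based screen coordinates (origin
#' top-left, y increasing downward), so the gaze pixel sits at 0-based
#' window index `[half, half]`. Cells falling off-screen are `NaN`. A
#' missing or off-screen gaze yields an all-`NaN` window, preserving time
#' alignment with the pupil series.
#'
#' @param frame `H x W x C` numeric array (one frame, any channel space).
#' @param gaze Length-2 numeric `(x, y)` in 0-based pixel coordinates;
#'   rounded to the nearest integer pixel.
#' @param half Window half-size in pixels (default 350 for a 700 px window).
#' @return `2*half x 2*half x C` array.
#' @export
extract_gaze_window <- function(frame, gaze, half = 350L) {
  d <- dim(frame)
  stopifnot(length(d) == 3L, half >= 1L)
  H <- d[1]; W <- d[2]; C <- d[3]
  n <- 2L * as.integer(half)
  out <- array(NaN, c(n, n, C))
  gx <- round(gaze[1]); gy <- round(gaze[2])
  if (!is.finite(gx) || !is.finite(gy) ||
      gx < 0 || gx > W - 1 || gy < 0 || gy > H - 1)
    return(out)
  rows <- (gy - half):(gy + half - 1L)  # 0-based screen rows
  cols <- (gx - half):(gx + half - 1L)
  rok <- rows >= 0L & rows <= H - 1L
  cok <- cols >= 0L & cols <= W - 1L
  out[which(rok), which(cok), ] <-
    frame[rows[rok] + 1L, cols[cok] + 1L, , drop = FALSE]
  out
}

#' Block-downsample a window by NaN-ignoring block means
#'
#' Each output cell is the mean of the non-`NaN` values in its
#' `factor x factor` block; an all-`NaN` block stays `NaN`.
#'
#' @param window `n1 x n2 x C` (or `n1 x n2`) numeric array; `factor` must
#'   divide `n1` and `n2`.
#' @param factor Block edge length in pixels (default 10).
#' @return `(n1/factor) x (n2/factor) x C` array.
#' @export
block_downsample <- function(window, factor = 10L) {
  factor <- as.integer(factor)
  d <- dim(window)
  if (length(d) == 2L) { window <- array(window, c(d, 1L)); d <- dim(window) }
  stopifnot(length(d) == 3L, factor >= 1L)
  if (d[1] %% factor != 0L || d[2] %% factor != 0L)
    stop("factor must divide both window dimensions")
  if (factor == 1L) return(window)
  n1 <- d[1] %/% factor; n2 <- d[2] %/% factor; C <- d[3]
  x <- window
  bad <- !is.finite(x)
  x[bad] <- 0
  cnt <- array(as.numeric(!bad), d)
  # collapse rows: (factor, n1, d2*C) -> colSums over dim 1
  sum1 <- colSums(array(x, c(factor, n1, d[2] * C)), dims = 1)
  cnt1 <- colSums(array(cnt, c(factor, n1, d[2] * C)), dims = 1)
  # collapse cols: reshape to (n1, factor, n2, C), permute factor first
  sum1 <- array(sum1, c(n1, factor, n2, C))
  cnt1 <- array(cnt1, c(n1, factor, n2, C))
  sum2 <- colSums(aperm(sum1, c(2, 1, 3, 4)), dims = 1)
  cnt2 <- colSums(aperm(cnt1, c(2, 1, 3, 4)), dims = 1)
  out <- sum2 / cnt2
  out[cnt2 == 0] <- NaN
  array(out, c(n1, n2, C))
}

#' Build a gaze-contingent window stack from frames and gaze samples
#'
#' For each frame, transforms pixels to the requested channel space,
#' extracts the gaze-centered window and block-downsamples it. Gaze samples
#' must already be at the frame rate (see [downsample_trace()] for pupil /
#' gaze resampling).
#'
#' @param frames A [frame_stack()].
#' @param gaze_x,gaze_y Numeric vectors (length = number of frames), 0-based
#'   pixel coordinates; `NaN` marks missing gaze.
#' @param half Window half-size in px (default 350).
#' @param factor Block-downsampling factor (default 10).
#' @param channel_space `"rgb_lum"`, `"cielab"` or `"none"`.
#' @param gamma [gamma_params()] used when `channel_space = "rgb_lum"`.
#' @return Object of class `gaze_window_stack`: list with `data`
#'   (`T x n x n x 3`, `n = 2*half/factor`), `channel_space`, `px_per_cell`,
#'   `fs`.
#' @export
gaze_window_stack <- function(frames, gaze_x, gaze_y, half = 350L,
                              factor = 10L,
                              channel_space = c("rgb_lum", "cielab", "none"),
                              gamma = gamma_params()) {
  stopifnot(inherits(frames, "frame_stack"))
  channel_space <- match.arg(channel_space)
  Tn <- dim(frames$frames)[1]
  stopifnot(length(gaze_x) == Tn, length(gaze_y) == Tn)
  n <- 2L * as.integer(half) %/% as.integer(factor)
  # frame-major staging array keeps per-frame writes contiguous; a single
  # aperm at the end yields the time-major public layout
  tmp <- array(NaN, c(n, n, 3L, Tn))
  fa <- aperm(frames$frames, c(2, 3, 4, 1))
  dhw <- dim(frames$frames)[2:4]
  # 8-bit input: the gamma map collapses to a 256-entry lookup table
  lut <- if (channel_space == "rgb_lum")
    vapply(1:3, function(c) gamma$scale[c] * ((0:255) / 255)^gamma$gamma[c],
           numeric(256))
  for (t in seq_len(Tn)) {
    fr <- fa[, , , t]
    dim(fr) <- dhw
    win <- extract_gaze_window(fr, c(gaze_x[t], gaze_y[t]), half = half)
    if (all(!is.finite(win))) next
    win <- switch(channel_space,
                  rgb_lum = {
                    w <- win
                    for (c in 1:3) w[, , c] <- lut[win[, , c] + 1L, c]
                    w
                  },
                  cielab = rgb_to_cielab(win),
                  none = win)
    tmp[, , , t] <- block_downsample(win, factor)
  }
  data <- aperm(tmp, c(4, 1, 2, 3))
  structure(list(data = data, channel_space = channel_space,
                 px_per_cell = as.integer(factor), fs = frames$fs),
            class = "gaze_window_stack")
}

#' Per-cell fraction of missing time points
#'
#' Off-screen coverage varies across the window (larger toward the edges on
#' the side the gaze hugs), which modulates the effective sample count per
#' cell.
#'
#' @param stack A `gaze_window_stack` or `T x n x n x C` array.
#' @return `n x n` matrix of fractions in `[0, 1]` (channel 1 pattern; the
#'   `NaN` pattern is identical across channels by construction).
#' @export
nan_fraction_map <- function(stack) {
  a <- if (inherits(stack, "gaze_window_stack")) stack$data else stack
  stopifnot(length(dim(a)) == 4L, dim(a)[1] >= 1L)
  colMeans(!is.finite(a[, , , 1, drop = FALSE])[, , , 1], dims = 1)
}
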
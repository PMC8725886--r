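#' Construct an epoch set for one subject
#'
#' Stimulus-locked pupil epochs on a common time grid. The canonical design
#' crosses 3 colors (red, green, blue) with 4 locations (top, bottom, left,
#' right), 5 repetitions each, at 1000 Hz over `[-500, +2500]` ms.
#'
#' @param time Numeric vector of epoch times in seconds (must cover at least
#'   `[-0.5, 2]`).
#' @param samples `trials x length(time)` numeric matrix of pupil size in
#'   device units; `NaN` marks missing samples.
#' @param color,location Character vectors (one entry per trial).
#' @param fs Sampling rate in Hz.
#' @return Object of class `epoch_set`.
#' @export
epoch_set <- function(time, samples, color, location, fs = 1000) {
  stopifnot(is.matrix(samples), length(time) == ncol(samples),
            length(color) == nrow(samples),
            length(location) == nrow(samples))
  if (min(time) > -0.5 + 1e-9 || max(time) < 2 - 1e-9)
    stop("epoch must cover at least [-500, 2000] ms")
  structure(list(time = time, samples = samples,
                 color = as.character(color),
                 location = as.character(location), fs = fs),
            class = "epoch_set")
}

#' Percent-signal-change normalization
#'
#' Each trial is normalized as `P(t) = 100 * (x(t) - B) / B`, with `B` the
#' mean of valid samples in the pre-stimulus baseline window `[-500, 0)` ms.
#' This removes device units, making trials and subjects comparable. Trials
#' with under 50% valid baseline samples or non-positive `B` are marked
#' invalid.
#'
#' @param epochs An [epoch_set()].
#' @return The `epoch_set` with `samples` in percent signal change, plus
#'   fields `baseline` (per-trial `B`, device units) and `baseline_valid`
#'   (logical per trial).
#' @export
percent_signal_change <- function(epochs) {
  stopifnot(inherits(epochs, "epoch_set"))
  bwin <- epochs$time >= -0.5 & epochs$time < 0
  B <- rep(NaN, nrow(epochs$samples))
  ok <- rep(FALSE, nrow(epochs$samples))
  for (i in seq_len(nrow(epochs$samples))) {
    b <- epochs$samples[i, bwin]
    if (mean(is.finite(b)) >= 0.5) {
      Bi <- mean(b[is.finite(b)])
      if (is.finite(Bi) && Bi > 0) { B[i] <- Bi; ok[i] <- TRUE }
    }
  }
  out <- epochs
  out$samples <- 100 * (epochs$samples - B) / B
  out$samples[!ok, ] <- NaN
  out$baseline <- B
  out$baseline_valid <- ok
  out
}

#' Trial validity: no blink or missing sample in the critical window
#'
#' A trial is valid when every sample in `(0, 1500]` ms is present and its
#' baseline passed [percent_signal_change()] (when available).
#'
#' @param epochs An `epoch_set` (normalized or raw).
#' @return Logical vector, one entry per trial.
#' @export
trial_valid <- function(epochs) {
  crit <- epochs$time > 0 & epochs$time <= 1.5
  v <- apply(is.finite(epochs$samples[, crit, drop = FALSE]), 1, all)
  if (!is.null(epochs$baseline_valid)) v <- v & epochs$baseline_valid
  v
}

#' Trial and subject quality control
#'
#' A subject is included iff (1) at least one valid trial exists for each of
#' the 12 color-by-location conditions and (2) at least 50% of all trials
#' are valid.
#'
#' @param epochs An `epoch_set`.
#' @param colors,locations Factor levels defining the full design.
#' @return List with `valid` (per-trial logical), `included` (scalar
#'   logical), `n_valid`, `n_total`, `per_condition` (named valid counts).
#' @export
qc_trials_and_subjects <- function(epochs, colors = .ps_colors,
                                   locations = .ps_locations) {
  v <- trial_valid(epochs)
  cond <- interaction(factor(epochs$color, colors),
                      factor(epochs$location, locations), drop = FALSE)
  tab <- tapply(v, cond, sum)
  tab[is.na(tab)] <- 0L
  included <- all(tab >= 1L) && mean(v) >= 0.5
  list(valid = v, included = included, n_valid = sum(v),
       n_total = length(v), per_condition = tab)
}

#' Condition-mean waveform and peak constriction
#'
#' Averages the valid trials of one condition point-wise and returns the
#' minimum of the mean waveform over `[0, 2000]` ms inclusive (PLRmin, the
#' peak pupillary constriction, in percent signal change).
#'
#' @param psc `trials x time` matrix in percent signal change (valid trials
#'   only).
#' @param time Epoch times in seconds.
#' @return List with `waveform` (mean across trials), `plr_min` and
#'   `t_min` (time of the minimum, s). Zero rows give `NaN` values.
#' @export
condition_waveform_and_plrmin <- function(psc, time) {
  if (is.null(dim(psc))) psc <- matrix(psc, nrow = 1)
  if (!nrow(psc))
    return(list(waveform = rep(NaN, length(time)), plr_min = NaN,
                t_min = NaN))
  wf <- colMeans(psc)
  win <- time >= 0 & time <= 2 + 1e-9
  i <- which(win)[which.min(wf[win])]
  list(waveform = wf, plr_min = wf[i], t_min = time[i])
}

#' Per-subject PLRmin table
#'
#' Runs normalization, QC and condition averaging for a list of subjects.
#'
#' @param subjects List of [epoch_set()] objects (raw device units).
#' @param colors,locations Design levels.
#' @return List with `plr_min` (`included_subjects x 3 x 4` array,
#'   dimnames set), `baseline` (same shape, device units), `included`
#'   (logical per input subject), `qc` (per-subject QC lists).
#' @export
plr_min_table <- function(subjects, colors = .ps_colors,
                          locations = .ps_locations) {
  S <- length(subjects)
  qcs <- vector("list", S)
  included <- logical(S)
  res <- array(NaN, c(S, length(colors), length(locations)),
               dimnames = list(NULL, colors, locations))
  bas <- res
  for (s in seq_len(S)) {
    ep <- percent_signal_change(subjects[[s]])
    qc <- qc_trials_and_subjects(ep, colors, locations)
    qcs[[s]] <- qc
    included[s] <- qc$included
    for (ci in seq_along(colors)) for (li in seq_along(locations)) {
      sel <- qc$valid & ep$color == colors[ci] & ep$location == locations[li]
      if (!any(sel)) next
      cw <- condition_waveform_and_plrmin(ep$samples[sel, , drop = FALSE],
                                          ep$time)
      res[s, ci, li] <- cw$plr_min
      bas[s, ci, li] <- mean(ep$baseline[sel])
    }
  }
  list(plr_min = res[included, , , drop = FALSE],
       baseline = bas[included, , , drop = FALSE],
       included = included, qc = qcs)
}

# Orthonormal Helmert-type contrasts for a k-level within factor.
orth_contrasts <- function(k) {
  C <- stats::contr.helmert(k)
  sweep(C, 2, sqrt(colSums(C^2)), "/")
}

# Greenhouse-Geisser epsilon from the covariance of orthonormal contrasts.
gg_epsilon <- function(S) {
  d <- nrow(S)
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  min(1, max(1 / d, eps))
}

# Mauchly's sphericity test on an orthonormal-contrast covariance matrix.
mauchly_p <- function(S, n) {
  d <- nrow(S)
  if (d < 2L) return(NA_real_)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) return(0)
  W <- prod(ev) / (mean(ev))^d
  f <- d * (d + 1) / 2 - 1
  chi <- -(n - 1 - (2 * d^2 + d + 2) / (6 * d)) * log(W)
  stats::pchisq(chi, f, lower.tail = FALSE)
}

#' Two-factor repeated-measures ANOVA (3 colors x 4 locations)
#'
#' Fully within-subject decomposition on a complete balanced table of
#' PLRmin values. Sphericity is assessed per effect with Mauchly's test;
#' the reported `p` is Greenhouse-Geisser corrected when Mauchly rejects at
#' .05 (and the raw F-test p otherwise); both `p_uncorrected` and `p_gg`
#' are always reported, along with partial and generalized eta squared.
#'
#' @param y `subjects x colors x locations` numeric array (subjects with
#'   any NaN cell are dropped with a warning).
#' @param factor_names Length-2 names for reporting.
#' @return Data frame of class `anova_table`, one row per effect
#'   (`color`, `location`, `color:location`) with columns `df1`, `df2`,
#'   `F`, `epsilon`, `df1_gg`, `df2_gg`, `p_uncorrected`, `p_gg`,
#'   `mauchly_p`, `p`, `pes`, `ges`.
#' @export
rm_anova_3x4 <- function(y, factor_names = c("color", "location")) {
  stopifnot(length(dim(y)) == 3L)
  ok <- apply(is.finite(y), 1, all)
  if (!all(ok)) {
    warning("dropping ", sum(!ok), " subject(s) with incomplete cells")
    y <- y[ok, , , drop = FALSE]
  }
  n <- dim(y)[1]; ka <- dim(y)[2]; kb <- dim(y)[3]
  if (n < 3L) stop("repeated-measures ANOVA needs at least 3 subjects")
  Y <- matrix(y, n, ka * kb)  # conditions ordered with color fastest
  Ca <- orth_contrasts(ka); Cb <- orth_contrasts(kb)
  ua <- rep(1, ka) / sqrt(ka); ub <- rep(1, kb) / sqrt(kb)
  # column-major layout of matrix(y): color varies fastest, location slowest
  K <- list(kronecker(ub, Ca),              # color
            kronecker(Cb, ua),              # location
            kronecker(Cb, Ca))              # interaction
  grand <- mean(Y)
  ss_subj <- ka * kb * sum((rowMeans(Y) - grand)^2)
  eff <- vector("list", 3L)
  ss_eff <- ss_err <- numeric(3L)
  for (i in 1:3) {
    D <- Y %*% K[[i]]
    dbar <- colMeans(D)
    ss_eff[i] <- n * sum(dbar^2)
    ss_err[i] <- sum(sweep(D, 2, dbar)^2)
    d1 <- ncol(D); d2 <- d1 * (n - 1)
    Fv <- (ss_eff[i] / d1) / (ss_err[i] / d2)
    Sc <- stats::cov(D)
    eps <- gg_epsilon(Sc)
    mp <- mauchly_p(Sc, n)
    p_raw <- stats::pf(Fv, d1, d2, lower.tail = FALSE)
    p_gg <- stats::pf(Fv, eps * d1, eps * d2, lower.tail = FALSE)
    eff[[i]] <- data.frame(
      effect = c(factor_names[1], factor_names[2],
                 paste(factor_names, collapse = ":"))[i],
      df1 = d1, df2 = d2, F = Fv, epsilon = eps,
      df1_gg = eps * d1, df2_gg = eps * d2,
      p_uncorrected = p_raw, p_gg = p_gg, mauchly_p = mp,
      p = if (is.finite(mp) && mp < 0.05) p_gg else p_raw,
      pes = ss_eff[i] / (ss_eff[i] + ss_err[i]),
      ges = NA_real_)
  }
  out <- do.call(rbind, eff)
  denom_all <- ss_subj + sum(ss_err)
  out$ges <- ss_eff / (ss_eff + denom_all)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' Planned difference-score tests with FDR
#'
#' For each color, `D_tb = PLRmin(top) - PLRmin(bottom)` and
#' `D_lr = PLRmin(left) - PLRmin(right)` are computed per subject and each
#' of the six scores is tested against 0 with a two-sided one-sample
#' t-test; Benjamini-Hochberg adjustment is applied across exactly these
#' six p-values.
#'
#' @param y `subjects x 3 x 4` PLRmin array with dimnames
#'   (`colors`, `locations`).
#' @param q FDR level (default 0.05).
#' @return Data frame with one row per color x orientation: `mean_diff`,
#'   `t`, `df`, `p`, `p_fdr`, `significant`.
#' @export
difference_score_tests <- function(y, q = 0.05) {
  stopifnot(length(dim(y)) == 3L)
  n <- dim(y)[1]
  if (n < 3L) stop("need at least 3 included subjects")
  colors <- dimnames(y)[[2]]
  pairs <- list(vertical = c("top", "bottom"),
                horizontal = c("left", "right"))
  rows <- list()
  for (ci in seq_along(colors)) for (or in names(pairs)) {
    d <- y[, ci, pairs[[or]][1]] - y[, ci, pairs[[or]][2]]
    if (stats::sd(d) == 0) {
      warning("degenerate variance for ", colors[ci], " ", or)
      tt <- list(statistic = c(t = if (mean(d) == 0) 0 else NaN),
                 parameter = c(df = n - 1), p.value = NaN)
    } else tt <- stats::t.test(d, mu = 0)
    rows[[length(rows) + 1L]] <- data.frame(
      color = colors[ci], orientation = or,
      contrast = paste(pairs[[or]], collapse = "-"),
      mean_diff = mean(d), t = unname(tt$statistic),
      df = unname(tt$parameter), p = tt$p.value)
  }
  out <- do.call(rbind, rows)
  fdr <- bh_fdr(out$p, q)
  out$p_fdr <- fdr$p_adj
  out$significant <- fdr$mask
  out
}
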
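#' Fisher Z transform
#'
#' `z = atanh(r)`; correlations are clipped to `|r| <= 1 - 1e-7` first so
#' that perfect correlations map to a large finite value. Variance
#' stabilization makes subject-wise correlation values approximately normal,
#' licensing t-based group inference.
#'
#' @param r Numeric array of correlations (`|r| <= 1`, NaN allowed).
#' @return Array of the same shape.
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1, na.rm = TRUE)) stop("|r| > 1 is not a correlation")
  atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r)))
}

#' Pixel-wise one-sample t-test map
#'
#' Tests each cell's distribution of subject values against 0. Cells with
#' fewer than `n_min` finite subjects are `NaN`; zero between-subject
#' variance gives `p = NaN` with a warning.
#'
#' @param z_stack `subjects x n x n` (or `subjects x n x n x C`) array,
#'   typically of Fisher-Z values.
#' @param n_min Minimum subjects per cell (default 3).
#' @return List of class `group_map_result` with `mean`, `t`, `p`, `df`,
#'   `n` arrays (each `n x n[ x C]`).
#' @export
one_sample_t_map <- function(z_stack, n_min = 3L) {
  d <- dim(z_stack)
  stopifnot(length(d) %in% c(3L, 4L))
  S <- d[1]
  M <- matrix(z_stack, S, prod(d[-1]))
  fin <- is.finite(M)
  n <- colSums(fin)
  M0 <- M; M0[!fin] <- 0
  mu <- ifelse(n > 0, colSums(M0) / n, NaN)
  ss <- colSums((M0 - rep(mu, each = S))^2 * fin)
  sdv <- ifelse(n > 1, sqrt(ss / (n - 1)), NaN)
  t <- mu / (sdv / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  low <- n < n_min
  mu[low] <- NaN; t[low] <- NaN; p[low] <- NaN
  if (any(sdv == 0 & !low, na.rm = TRUE)) {
    warning("zero between-subject variance at some cells; p set to NaN")
    z0 <- which(sdv == 0 & !low)
    t[z0] <- NaN; p[z0] <- NaN
  }
  shp <- d[-1]
  structure(list(mean = array(mu, shp), t = array(t, shp),
                 p = array(p, shp), df = array(n - 1, shp),
                 n = array(n, shp)),
            class = "group_map_result")
}

#' Benjamini-Hochberg step-up FDR control
#'
#' Over the finite p-values, finds the largest `i` with
#' `p_(i) <= q * i / m` and rejects all hypotheses with `p <= p_(i)`.
#' Adjusted p-values are the usual step-up ones (monotone non-decreasing in
#' raw-p rank). `NaN` entries are excluded and never rejected.
#'
#' @param p Numeric vector, matrix or array of p-values in `[0, 1]` or NaN.
#' @param q FDR level.
#' @return List with `mask` (logical, same shape; `FALSE` at NaN) and
#'   `p_adj` (same shape).
#' @export
bh_fdr <- function(p, q) {
  stopifnot(q > 0, q < 1)
  shp <- dim(p)
  pv <- as.vector(p)
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  fin <- which(is.finite(pv))
  mask <- rep(FALSE, length(pv))
  padj <- rep(NaN, length(pv))
  if (length(fin)) {
    ps <- pv[fin]
    m <- length(ps)
    o <- order(ps)
    ranked <- ps[o]
    adj <- rev(cummin(rev(ranked * m / seq_len(m))))
    adj <- pmin(adj, 1)
    cutoff_i <- which(ranked <= q * seq_len(m) / m)
    if (length(cutoff_i)) {
      thr <- ranked[max(cutoff_i)]
      mask[fin] <- pv[fin] <= thr
    }
    padj_f <- numeric(m)
    padj_f[o] <- adj
    padj[fin] <- padj_f
  }
  if (!is.null(shp)) { dim(mask) <- shp; dim(padj) <- shp }
  list(mask = mask, p_adj = padj)
}

#' Williams (Hotelling-Williams) t for dependent overlapping correlations
#'
#' Tests `H0: rho12 = rho13` when both correlations share variable 1 (here:
#' the pupil series correlated with two color channels), accounting for the
#' channels' own correlation `r23`. `t = 0` when `r12 = r13`; the sign of
#' `t` is the sign of `r12 - r13`; `df = n - 3`.
#'
#' @param r12,r13 Correlations of the shared variable with variables 2, 3.
#' @param r23 Correlation between variables 2 and 3.
#' @param n Paired sample count (> 3).
#' @return List with `t` and `df` (arrays matching the inputs).
#' @export
williams_t <- function(r12, r13, r23, n) {
  if (any(n <= 3)) stop("Williams t requires n > 3")
  if (any(abs(c(r12, r13, r23)) > 1, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  if (any(detR < -1e-8, na.rm = TRUE))
    stop("incoherent correlation triple: negative determinant")
  detR <- pmax(detR, 0)
  rbar <- (r12 + r13) / 2
  den2 <- 2 * detR * (n - 1) / (n - 3) + rbar^2 * (1 - r23)^3
  t <- (r12 - r13) * sqrt((n - 1) * (1 + r23) / den2)
  t[r12 == r13] <- 0  # covers den2 -> 0 degeneracies at equality
  list(t = t, df = n - 3)
}

#' Steiger Z for dependent overlapping correlations
#'
#' Asymptotic alternative to [williams_t()], based on Fisher-Z differences
#' with a pooled-correlation estimate of their covariance.
#'
#' @inheritParams williams_t
#' @return List with `z` (standard normal under H0).
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (any(n <= 3)) stop("Steiger Z requires n > 3")
  rbar <- (r12 + r13) / 2
  num <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  psi <- num / (1 - rbar^2)^2
  z <- (atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r12))) -
        atanh(pmin(1 - 1e-7, pmax(-(1 - 1e-7), r13)))) *
    sqrt((n - 3) / (2 - 2 * psi))
  z[r12 == r13] <- 0
  list(z = z)
}

#' Group map of dependent-correlation channel differences
#'
#' Per subject and cell, computes the Williams t (or Steiger z) for the
#' difference between two channels' correlations with pupil size; the
#' per-subject statistics are then aggregated across subjects by a per-cell
#' one-sample t-test against 0 and thresholded by BH FDR.
#'
#' @param maps_a,maps_b Lists (one per subject) of `n x n` correlation
#'   matrices of each channel with pupil size.
#' @param r23_maps List of `n x n` matrices: per-subject correlation between
#'   the two channels' cell series.
#' @param n_time Integer vector: paired time samples per subject.
#' @param q FDR level (default 0.01).
#' @param method `"williams"` or `"steiger"`.
#' @return List of class `dependent_comparison`: `stat` (subjects stack),
#'   `group` (a `group_map_result`), `q_mask`, `p_adj`, `q`, `method`.
#' @export
dependent_comparison_map <- function(maps_a, maps_b, r23_maps, n_time,
                                     q = 0.01,
                                     method = c("williams", "steiger")) {
  method <- match.arg(method)
  S <- length(maps_a)
  stopifnot(length(maps_b) == S, length(r23_maps) == S,
            length(n_time) == S)
  if (S < 2L) stop("group aggregation needs at least 2 subjects")
  if (!is.matrix(maps_a[[1]])) stop("per-subject maps must be matrices")
  dm <- dim(maps_a[[1]])
  stat <- array(NaN, c(S, dm))
  for (s in seq_len(S)) {
    st <- if (method == "williams")
      williams_t(maps_a[[s]], maps_b[[s]], r23_maps[[s]], n_time[s])$t
    else steiger_z(maps_a[[s]], maps_b[[s]], r23_maps[[s]], n_time[s])$z
    stat[s, , ] <- st
  }
  grp <- one_sample_t_map(stat)
  fdr <- bh_fdr(grp$p, q)
  structure(list(stat = stat, group = grp, q_mask = fdr$mask,
                 p_adj = fdr$p_adj, q = q, method = method),
            class = "dependent_comparison")
}

#' Compare correlations above versus below fixation
#'
#' Welch two-sample t-test between the finite cells strictly above the
#' central row and strictly below it (the central row itself is excluded).
#' A negative t means the upper cells are more negative (stronger inverse
#' coupling with pupil size above fixation).
#'
#' @param map `n x n` correlation matrix for one channel (n even; with
#'   `n = 70` the upper half is 0-based rows `< 35`, lower `> 35`).
#' @param min_cells Minimum finite cells required per half (default 10).
#' @return List with `t`, `p`, `df`, `mean_upper`, `mean_lower`.
#' @export
upper_lower_test <- function(map, min_cells = 10L) {
  stopifnot(is.matrix(map))
  n <- nrow(map)
  mid <- n %/% 2L + 1L  # 1-based row of the 0-based index n/2
  upper <- as.vector(map[seq_len(mid - 1L), ])
  lower <- as.vector(map[seq(mid + 1L, n), ])
  upper <- upper[is.finite(upper)]
  lower <- lower[is.finite(lower)]
  if (length(upper) < min_cells || length(lower) < min_cells)
    stop("insufficient finite cells in one half")
  tt <- stats::t.test(upper, lower)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter),
       mean_upper = mean(upper), mean_lower = mean(lower))
}
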
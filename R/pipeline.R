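#' Simulate a cohort for the free-viewing analysis
#'
#' Generates, per subject, a scene, a gaze trajectory and a pupil trace
#' with known ground truth. Subject seeds are derived deterministically
#' from `seed`.
#'
#' @param n_subjects Number of subjects (default 34).
#' @param scene_cfg Template [scene_sim_config()] (per-subject seeds are
#'   substituted).
#' @param pupil_cfg Template [pupil_sim_config()].
#' @param gaze_args Named list of extra arguments for [simulate_gaze()]
#'   (screen geometry defaults are taken from `scene_cfg`).
#' @param seed Master seed.
#' @return List of subjects, each `list(frames, gaze, pupil, truth)`.
#' @export
simulate_experiment1 <- function(n_subjects = 34L,
                                 scene_cfg = scene_sim_config(),
                                 pupil_cfg = pupil_sim_config(),
                                 gaze_args = list(), seed = 1L) {
  seeds <- child_seeds(seed, 3L * n_subjects)
  out <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    sc <- scene_cfg; sc$seed <- seeds[3 * s - 2]
    frames <- simulate_scene(sc)
    dur <- sc$n_frames / sc$fs
    ga <- utils::modifyList(
      list(n = as.integer(round(dur * pupil_cfg$fs)), fs = pupil_cfg$fs,
           H = sc$H, W = sc$W, horizon_row = sc$horizon_row,
           seed = seeds[3 * s - 1]),
      gaze_args)
    gaze <- do.call(simulate_gaze, ga)
    pc <- pupil_cfg; pc$seed <- seeds[3 * s]
    sim <- simulate_pupil_from_scene(frames, gaze, pc,
                                     half = dim(pc$kernel)[1] %/% 2L *
                                       scene_px_per_cell(sc, pc),
                                     factor = scene_px_per_cell(sc, pc))
    out[[s]] <- list(frames = frames, gaze = gaze, pupil = sim$trace,
                     truth = sim$truth)
  }
  out
}

# Pixels per map cell implied by the scene scale: 10 at full resolution
# (1080-px screens), 1 for reduced-resolution scenes under ~200 px.
scene_px_per_cell <- function(scene_cfg, pupil_cfg) {
  if (scene_cfg$H >= 700L) 10L else 1L
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the free-viewing correlation-map analysis end to end
#'
#' Per subject: pupil preprocessing to the frame rate, gaze-contingent
#' window extraction in the requested channel space, alignment at a fixed
#' lag (default 500 ms = 6 frames at 12 Hz), and a pixel-wise correlation
#' map. At the group level: Fisher-Z one-sample t maps with BH FDR,
#' dependent-correlation channel comparisons (blue-red, green-red,
#' blue-green), per-subject above-vs-below-fixation tests on the blue
#' channel, per-subject empirical lag estimates and the NaN-fraction map.
#'
#' @param subjects List as from [simulate_experiment1()]: each element has
#'   `frames`, `gaze` (data frame `time`,`x`,`y`), `pupil` (raw
#'   [pupil_trace()]). An element may instead be a zero-argument function
#'   returning such a list; it is called (and its output discarded) when
#'   the subject is processed, which keeps only one subject's frames in
#'   memory at a time for large cohorts.
#' @param config A [read_run_config()] list (or named list of overrides).
#' @param out_dir Optional directory; when given, maps and a run manifest
#'   are written via [write_map_bundle()].
#' @param half,factor Window geometry; defaults follow
#'   `config$window_half` / `config$downsample_factor`.
#' @return List of class `exp1_result`: `per_subject` (correlation maps),
#'   `group` (per-channel `group_map_result` + FDR masks), `comparisons`,
#'   `upper_lower` (per-subject data frame), `lags`, `nan_map`, `config`.
#' @export
run_experiment1 <- function(subjects, config = list(), out_dir = NULL,
                            half = NULL, factor = NULL) {
  cfg <- read_run_config(config)
  if (is.null(half)) half <- cfg$window_half
  if (is.null(factor)) factor <- cfg$downsample_factor
  S <- length(subjects)
  if (S < 2L) stop("stage 'input': need at least 2 subjects")
  gp <- gamma_params(cfg$gamma[1], cfg$gamma[2], cfg$gamma[3])
  params <- preprocess_params(k1 = cfg$k1, k2 = cfg$k2,
                              blink_pad_ms = cfg$blink_pad_ms,
                              hann_ms = cfg$hann_ms,
                              blink_min_ms = cfg$blink_min_ms,
                              blink_max_ms = cfg$blink_max_ms,
                              target_fs = cfg$target_fs)
  lag <- lag_ms_to_frames(cfg$lag_ms, cfg$target_fs)
  maps <- vector("list", S)
  r23 <- list(br = vector("list", S), gr = vector("list", S),
              bg = vector("list", S))
  lags <- vector("list", S)
  n_time <- integer(S)
  nan_acc <- NULL
  for (s in seq_len(S)) {
    sub <- subjects[[s]]
    if (is.function(sub)) sub <- sub()
    pp <- stage("preprocess", preprocess_pupil(sub$pupil, params = params))
    Tn <- dim(sub$frames$frames)[1]
    gx <- stage("gaze", downsample_trace(
      pupil_trace(sub$gaze$x, sub$pupil$fs, time = sub$gaze$time),
      cfg$target_fs)$value[seq_len(Tn)])
    gy <- downsample_trace(
      pupil_trace(sub$gaze$y, sub$pupil$fs, time = sub$gaze$time),
      cfg$target_fs)$value[seq_len(Tn)]
    stack <- stage("windows", gaze_window_stack(
      sub$frames, gx, gy, half = half, factor = factor,
      channel_space = cfg$channel_space, gamma = gp))
    pv <- pp$value[seq_len(min(length(pp$value), Tn))]
    length(pv) <- Tn
    drive <- stage("drive", window_drive(stack))
    lags[[s]] <- tryCatch(
      lapply(1:3, function(c) estimate_lag(pv, drive[, c],
                                           fs = cfg$target_fs)),
      error = function(e) NULL)
    pa <- stage("align", shift_pupil(pv, lag))
    tr_stack <- stack
    tr_stack$data <- stack$data[seq_len(Tn - lag), , , , drop = FALSE]
    maps[[s]] <- stage("corrmap",
                       pixel_correlation_map(pa, tr_stack, lag_frames = lag))
    r23$br[[s]] <- channel_channel_map(tr_stack, 3, 1)
    r23$gr[[s]] <- channel_channel_map(tr_stack, 2, 1)
    r23$bg[[s]] <- channel_channel_map(tr_stack, 3, 2)
    n_time[s] <- Tn - lag
    nm <- nan_fraction_map(stack)
    nan_acc <- if (is.null(nan_acc)) nm else nan_acc + nm
    rm(sub, stack, tr_stack)   # frames are large; free before next subject
  }
  nan_map <- nan_acc / S
  n <- dim(maps[[1]]$r)[1]
  z <- array(NaN, c(S, n, n, 3))
  for (s in seq_len(S)) z[s, , , ] <- fisher_z(maps[[s]]$r)
  group <- lapply(1:3, function(c) {
    g <- stage("group", one_sample_t_map(z[, , , c]))
    fdr <- bh_fdr(g$p, cfg$fdr_q)
    g$q_mask <- fdr$mask; g$p_adj <- fdr$p_adj; g$q <- cfg$fdr_q
    g
  })
  names(group) <- c("ch1", "ch2", "ch3")
  ch_maps <- function(c) lapply(maps, function(m) m$r[, , c])
  comparisons <- stage("comparisons", list(
    blue_red = dependent_comparison_map(ch_maps(3), ch_maps(1), r23$br,
                                        n_time, q = cfg$fdr_q),
    green_red = dependent_comparison_map(ch_maps(2), ch_maps(1), r23$gr,
                                         n_time, q = cfg$fdr_q),
    blue_green = dependent_comparison_map(ch_maps(3), ch_maps(2), r23$bg,
                                          n_time, q = cfg$fdr_q)))
  ul <- stage("upper_lower", do.call(rbind, lapply(seq_len(S), function(s) {
    r <- upper_lower_test(maps[[s]]$r[, , 3])
    data.frame(subject = s, t = r$t, p = r$p,
               mean_upper = r$mean_upper, mean_lower = r$mean_lower)
  })))
  res <- structure(list(per_subject = maps, group = group,
                        comparisons = comparisons, upper_lower = ul,
                        lags = lags, nan_map = nan_map, config = cfg),
                   class = "exp1_result")
  if (!is.null(out_dir)) write_exp1_bundle(res, out_dir)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_exp1_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (c in 1:3) {
    g <- res$group[[c]]
    write_map_bundle(list(mean_z = g$mean, t = g$t, p = g$p,
                          q_mask = g$q_mask * 1),
                     file.path(out_dir, paste0("group_ch", c)),
                     meta = list(statistic = "one_sample_t_on_fisher_z",
                                 q = g$q, channel = c))
  }
  for (nm in names(res$comparisons)) {
    cmp <- res$comparisons[[nm]]
    write_map_bundle(list(t = cmp$group$t, p = cmp$group$p,
                          q_mask = cmp$q_mask * 1),
                     file.path(out_dir, paste0("cmp_", nm)),
                     meta = list(statistic = paste0("dependent_",
                                                    cmp$method),
                                 q = cmp$q))
  }
  write_map_bundle(list(nan_fraction = res$nan_map),
                   file.path(out_dir, "nan_map"),
                   meta = list(statistic = "nan_fraction"))
  utils::write.table(res$upper_lower,
                     file.path(out_dir, "upper_lower.csv"),
                     sep = ",", row.names = FALSE)
  write_manifest(out_dir, res$config)
  invisible(out_dir)
}

# Polynomial rolling hash of the serialized config, for the run manifest.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                      digits = NA))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

write_manifest <- function(out_dir, cfg) {
  manifest <- list(package = "pupilscape",
                   version = as.character(utils::packageVersion("pupilscape")),
                   config = unclass(cfg),
                   config_hash = config_hash(cfg),
                   seed = cfg$seed,
                   files = list.files(out_dir, recursive = TRUE),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the flashed-stimulus analysis end to end
#'
#' Normalization to percent signal change, trial and subject QC, PLRmin
#' extraction, the 3x4 repeated-measures ANOVA with Greenhouse-Geisser
#' handling, and the six planned difference-score tests with BH FDR.
#'
#' @param subjects List of [epoch_set()] objects (raw device units).
#' @param q FDR level for the difference scores (default 0.05).
#' @param out_dir Optional output directory for CSV/JSON results.
#' @return List of class `exp2_result`: `qc`, `plr_min`, `baseline`,
#'   `anova`, `diff_scores`, `n_included`.
#' @export
run_experiment2 <- function(subjects, q = 0.05, out_dir = NULL) {
  if (!length(subjects)) stop("stage 'input': empty trial set")
  tab <- stage("plrmin", plr_min_table(subjects))
  if (!any(tab$included))
    stop("stage 'qc': all subjects excluded; QC: ",
         paste(vapply(tab$qc, function(x)
           sprintf("%d/%d", x$n_valid, x$n_total), ""), collapse = " "))
  an <- stage("anova", rm_anova_3x4(tab$plr_min))
  ds <- stage("diff_scores", difference_score_tests(tab$plr_min, q = q))
  res <- structure(list(qc = tab$qc, plr_min = tab$plr_min,
                        baseline = tab$baseline, anova = an,
                        diff_scores = ds,
                        n_included = sum(tab$included),
                        included = tab$included),
                   class = "exp2_result")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(as.data.frame(an),
                       file.path(out_dir, "anova.csv"), sep = ",",
                       row.names = FALSE)
    utils::write.table(ds, file.path(out_dir, "diff_scores.csv"),
                       sep = ",", row.names = FALSE)
    pm <- res$plr_min
    flat <- data.frame(subject = rep(seq_len(dim(pm)[1]), 12),
                       color = rep(rep(dimnames(pm)[[2]], each = dim(pm)[1]),
                                   4),
                       location = rep(dimnames(pm)[[3]],
                                      each = dim(pm)[1] * 3),
                       plr_min = as.vector(pm))
    utils::write.table(flat, file.path(out_dir, "plr_min.csv"), sep = ",",
                       row.names = FALSE)
    write_manifest(out_dir, read_run_config(list(fdr_q = q)))
  }
  res
}
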
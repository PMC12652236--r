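# Shared fixtures: all synthetic, generated at test time.
# Simulated sessions run at 2 kHz (divisible by 400, as the response-window
# arithmetic requires); the 20 kHz case is exercised where the column-count
# arithmetic itself is under test.

fast_config <- function(n_trials = 200L, fs_lfp = 2000, ...) {
  session_config(n_trials = n_trials, fs_lfp = fs_lfp, include_eye = FALSE,
                 ...)
}

# No deviance effect, no adaptation: every trial shares the same gain.
null_config <- function(seed, ...) {
  fast_config(gain_deviant = 1, gain_standard = 1, gain_standard_initial = 1,
              adaptation_tau_trials = Inf, seed = seed, ...)
}

# Minimal hand-built trial log.
mini_log <- function(onsets, condition, stim = 2) {
  derive_trial_flags(data.frame(
    trial_index = seq_along(onsets) - 1L,
    onset_s = onsets, offset_s = onsets + stim,
    condition = condition, pos_col = 0L, pos_row = 0L))
}

# Hand-built continuous recording.
mini_rec <- function(v, fs, t0 = 0) {
  structure(list(voltage = matrix(v, nrow = 1), fs = fs, t0 = t0),
            class = "continuous_recording")
}

# Long-format keypoint rows for one point across frames.
kp_rows <- function(point, time_s, x, y, likelihood = 1) {
  data.frame(frame = seq_along(time_s) - 1L, time_s = time_s,
             point_name = point, x_px = x, y_px = y,
             likelihood = likelihood, stringsAsFactors = FALSE)
}

# Exhaustive permutation oracle: exact p over all label assignments.
exhaustive_perm_p <- function(a, b) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  obs <- abs(mean(a) - mean(b))
  cmb <- utils::combn(n, na)
  d <- apply(cmb, 2, function(idx)
    abs(mean(pool[idx]) - mean(pool[-idx])))
  mean(d >= obs - 1e-12)
}

# One frame of pupil-outline keypoints around a pupil centre (px, py), plus
# a circular socket annotation.
eye_fixture <- function(px, py, r = 50, center = c(240, 240)) {
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  kp <- do.call(rbind, lapply(seq_along(ang), function(k)
    kp_rows(sprintf("pupil_%d", k), 0,
            px + 4 * cos(ang[k]), py + 3 * sin(ang[k]))))
  soc_ang <- seq(0, 2 * pi, length.out = 13)[-13]
  socket <- data.frame(point_name = "socket",
                       x_px = center[1] + r * cos(soc_ang),
                       y_px = center[2] + r * sin(soc_ang))
  list(kp = kp, socket = socket)
}

# Null-calibration cache: nPC1(Deviant) over n independent null sessions,
# computed once per test run and shared between calibration checks (the
# ratio-1 condition IS the null condition). Runs at 400 Hz: block size 1,
# and the window covariance is dominated by the band-limited 1/f component,
# so the score statistics match the higher-rate conditions.
.calib_env <- new.env(parent = emptyenv())
null_npc1_deviant <- function(n = 400) {
  key <- paste0("n", n)
  if (is.null(.calib_env[[key]])) {
    .calib_env[[key]] <- vapply(seq_len(n), function(i) {
      s <- generate_oddball_session(null_config(10000 + i, fs_lfp = 400))
      m <- extract_response_matrix(s$rec, s$log)
      fit <- fit_balanced_pc1(m, s$log, seed = 20000 + i)
      npc1(project_scores(m, fit, s$log))[["deviant"]]
    }, numeric(1))
  }
  .calib_env[[key]]
}

# Score table built directly from scores + conditions (for unit tests of the
# permutation wrappers without running the PCA).
mini_scores <- function(score, condition, is_first10 = NULL,
                        angle_group = NULL, is_first_view = NULL) {
  n <- length(score)
  df <- data.frame(trial_index = seq_len(n) - 1L, condition = condition,
                   score = score,
                   is_first10 = if (is.null(is_first10)) rep(FALSE, n) else is_first10,
                   is_1after = FALSE, stringsAsFactors = FALSE)
  if (!is.null(angle_group)) df$angle_group <- angle_group
  if (!is.null(is_first_view)) df$is_first_view <- is_first_view
  df
}
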
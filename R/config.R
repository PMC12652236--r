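#' Default stimulus grid
#'
#' Five positions on a 3-by-3 screen grid (the four corners and the middle),
#' with one corner used as the frequent "standard" position and the opposite
#' corner as the rare "deviant" position.
#'
#' @param standard,deviant Row indices (into `positions`) of the standard and
#'   deviant positions.
#' @return A list with `positions` (data.frame of 0-based `col`, `row`),
#'   `standard` and `deviant` indices.
#' @export
default_grid <- function(standard = 1L, deviant = 5L) {
  positions <- data.frame(
    col = c(0L, 2L, 1L, 0L, 2L),
    row = c(0L, 0L, 1L, 2L, 2L)
  )
  if (standard == deviant) stop("grid: standard and deviant must differ")
  list(positions = positions, standard = as.integer(standard),
       deviant = as.integer(deviant))
}

#' Build a synthetic-session configuration
#'
#' Collects every tunable of the synthetic oddball/control session generator:
#' stimulation schedule, evoked-potential shape, position-specific adaptation,
#' background noise, head-angle kinematics, movement epochs and the
#' eye-camera geometry. All invariants are validated; a violated invariant
#' raises an error naming the offending field.
#'
#' Timing follows the oddball paradigm: each stimulus lasts
#' `stim_duration_s` (default 2 s) with an `isi_s` (default 5 s) black-screen
#' interval, and the deviant position receives a fraction `deviant_prob`
#' (default 1/10) of the trials.
#'
#' @param n_trials Number of stimulus trials.
#' @param deviant_prob Fraction of trials at the deviant position (in (0,1)).
#' @param stim_duration_s,isi_s,lead_in_s Stimulus duration, inter-stimulus
#'   interval and pre-session lead-in, seconds.
#' @param grid Stimulus grid, see [default_grid()].
#' @param fs_lfp LFP sampling rate, Hz; must be divisible by 400 so that the
#'   80--580 ms response window downsamples to exactly 200 points.
#' @param fs_video_head,fs_video_eye Video frame rates, Hz.
#' @param n_channels,channel_gains Number of recorded channels and the
#'   per-channel scaling of the evoked component.
#' @param gain_deviant Evoked gain of deviant trials.
#' @param gain_standard Asymptotic evoked gain of fully adapted standards.
#' @param gain_standard_initial Evoked gain of the first presentation at a
#'   position; decays exponentially toward `gain_standard`.
#' @param adaptation_tau_trials Adaptation time constant, in presentations at
#'   a position. `Inf` disables adaptation.
#' @param retinotopic If `TRUE`, adaptation is keyed to the gaze-relative
#'   position (screen position crossed with a `angle_bin_deg` head-angle bin)
#'   instead of the allocentric screen position.
#' @param angle_bin_deg Head-angle bin width for the retinotopic regime.
#' @param evoked_amp_uv,evoked_freq_hz,evoked_decay_s Evoked template:
#'   amplitude (microvolt), oscillation frequency and exponential decay.
#' @param evoked_onset_s,evoked_dur_s Template latency after stimulus onset
#'   and total template duration, seconds.
#' @param noise_sd_uv Background noise standard deviation, microvolt.
#' @param noise_pink_frac Fraction of noise variance carried by a 1/f
#'   component (the rest is white).
#' @param noise_highpass_hz Corner of the first-order high-pass applied to
#'   the 1/f component, emulating the AC coupling of the amplifier chain
#'   (default 1 Hz).
#' @param head_walk_sd_deg Per-frame standard deviation of the head-angle
#'   random walk, degrees.
#' @param head_angle_bound_deg Reflecting bound of the walk, degrees.
#' @param head_len_px,head_center_px,head_noise_px Head keypoint geometry:
#'   rostral--caudal distance, head-centre pixel, keypoint jitter.
#' @param still_trial_frac Fraction of trials whose 0--400 ms window freezes
#'   the head walk.
#' @param move_rate_per_min Expected rate of injected head-movement epochs
#'   (placed inside inter-stimulus intervals).
#' @param move_amp_deg,move_dur_s Amplitude and duration of a head-movement
#'   excursion.
#' @param movement_lfp_gain Evoked-template gain attached to movement epochs
#'   (0 = movement-silent LFP).
#' @param include_eye Generate the eye-camera stream?
#' @param eye_walk_sd_deg Per-frame sd of the eye-angle random walk, degrees.
#' @param eye_move_rate_per_min,eye_move_amp_deg,eye_move_dur_s Injected eye
#'   movement epochs (saccade-like pulses).
#' @param socket_radius_px,socket_center_px Eye-socket circle in the eye
#'   video, pixels.
#' @param pupil_axes_px,pupil_tilt_deg,n_pupil_points Pupil-outline ellipse
#'   semi-axes, tilt and number of tracked outline points.
#' @param eye_noise_px Keypoint jitter on pupil-outline points, pixels.
#' @param rho_deg Visual-streak angle relative to the video x axis, degrees.
#' @param lowlik_frac Fraction of keypoint rows assigned low likelihood (to
#'   exercise confidence filtering).
#' @param artifact_uv Artifact threshold on absolute voltage, microvolt.
#' @param seed Integer seed; fully determines the generated session.
#' @return An object of class `session_config` (a validated list).
#' @export
session_config <- function(n_trials = 200L,
                           deviant_prob = 0.1,
                           stim_duration_s = 2,
                           isi_s = 5,
                           lead_in_s = 5,
                           grid = default_grid(),
                           fs_lfp = 20000,
                           fs_video_head = 15,
                           fs_video_eye = 60,
                           n_channels = 1L,
                           channel_gains = rep(1, n_channels),
                           gain_deviant = 3,
                           gain_standard = 1,
                           gain_standard_initial = 3,
                           adaptation_tau_trials = 2,
                           retinotopic = FALSE,
                           angle_bin_deg = 5,
                           evoked_amp_uv = 100,
                           evoked_freq_hz = 20,
                           evoked_decay_s = 0.15,
                           evoked_onset_s = 0.08,
                           evoked_dur_s = 1.0,
                           noise_sd_uv = 50,
                           noise_pink_frac = 0.5,
                           noise_highpass_hz = 1,
                           head_walk_sd_deg = 1,
                           head_angle_bound_deg = 45,
                           head_len_px = 40,
                           head_center_px = c(320, 240),
                           head_noise_px = 0,
                           still_trial_frac = 0,
                           move_rate_per_min = 0,
                           move_amp_deg = 20,
                           move_dur_s = 0.4,
                           movement_lfp_gain = 0,
                           include_eye = TRUE,
                           eye_walk_sd_deg = 0.2,
                           eye_move_rate_per_min = 0,
                           eye_move_amp_deg = 10,
                           eye_move_dur_s = 0.15,
                           socket_radius_px = 50,
                           socket_center_px = c(240, 240),
                           pupil_axes_px = c(12, 9),
                           pupil_tilt_deg = 20,
                           n_pupil_points = 8L,
                           eye_noise_px = 0,
                           rho_deg = 15,
                           lowlik_frac = 0,
                           artifact_uv = 900,
                           seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "session_config"
  validate_session_config(cfg)
  cfg
}

validate_session_config <- function(cfg) {
  fail <- function(field, msg) {
    stop(sprintf("invalid session_config: field '%s' %s", field, msg),
         call. = FALSE)
  }
  num1 <- function(field, lo = -Inf, allow_inf = FALSE) {
    x <- cfg[[field]]
    if (!is.numeric(x) || length(x) != 1L || is.na(x))
      fail(field, "must be a single number")
    if (!allow_inf && !is.finite(x)) fail(field, "must be finite")
    if (x < lo) fail(field, sprintf("must be >= %s", lo))
    x
  }
  if (!is.numeric(cfg$n_trials) || length(cfg$n_trials) != 1L ||
      cfg$n_trials < 1 || cfg$n_trials != round(cfg$n_trials))
    fail("n_trials", "must be a positive integer")
  if (!is.numeric(cfg$deviant_prob) || length(cfg$deviant_prob) != 1L ||
      cfg$deviant_prob <= 0 || cfg$deviant_prob >= 1)
    fail("deviant_prob", "must lie in (0, 1)")
  num1("stim_duration_s", lo = 0)
  num1("isi_s", lo = 0)
  num1("lead_in_s", lo = 0)
  fs <- num1("fs_lfp", lo = 400)
  if (fs %% 400 != 0)
    fail("fs_lfp", "must be divisible by 400 (so the response window downsamples to an integer count)")
  num1("fs_video_head", lo = 1)
  num1("fs_video_eye", lo = 1)
  for (f in c("gain_deviant", "gain_standard", "gain_standard_initial"))
    if (num1(f) < 0) fail(f, "must be >= 0")
  num1("adaptation_tau_trials", lo = 0, allow_inf = TRUE)
  num1("noise_sd_uv", lo = 0)
  if (cfg$noise_pink_frac < 0 || cfg$noise_pink_frac > 1)
    fail("noise_pink_frac", "must lie in [0, 1]")
  num1("head_walk_sd_deg", lo = 0)
  num1("socket_radius_px", lo = 1)
  num1("artifact_uv", lo = 0)
  if (length(cfg$channel_gains) != cfg$n_channels)
    fail("channel_gains", "must have length n_channels")
  if (cfg$n_pupil_points < 5)
    fail("n_pupil_points", "must be >= 5 (ellipse fit well-posed)")
  if (cfg$lowlik_frac < 0 || cfg$lowlik_frac > 1)
    fail("lowlik_frac", "must lie in [0, 1]")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L ||
      cfg$seed != round(cfg$seed))
    fail("seed", "must be a single integer")
  p <- cfg$grid$positions
  if (is.null(p) || !all(c("col", "row") %in% names(p)))
    fail("grid", "must contain positions with 'col' and 'row'")
  if (cfg$grid$standard < 1 || cfg$grid$standard > nrow(p) ||
      cfg$grid$deviant < 1 || cfg$grid$deviant > nrow(p))
    fail("grid", "standard/deviant indices must point into positions")
  invisible(cfg)
}

#' @export
print.session_config <- function(x, ...) {
  cat("<session_config>\n")
  cat(sprintf("  %d trials (deviant_prob %.2f), stim %.1f s + ISI %.1f s\n",
              x$n_trials, x$deviant_prob, x$stim_duration_s, x$isi_s))
  cat(sprintf("  LFP %g Hz x %d channel(s); noise %.0f uV (pink frac %.2f)\n",
              x$fs_lfp, x$n_channels, x$noise_sd_uv, x$noise_pink_frac))
  cat(sprintf("  gains: deviant %.2f, standard %.2f (initial %.2f, tau %.1f), %s adaptation\n",
              x$gain_deviant, x$gain_standard, x$gain_standard_initial,
              x$adaptation_tau_trials,
              if (x$retinotopic) "retinotopic" else "allocentric"))
  invisible(x)
}

#' Total duration of a configured session in seconds
#' @param config A [session_config()].
#' @return Seconds from recording start to end.
#' @export
session_duration <- function(config) {
  config$lead_in_s +
    config$n_trials * (config$stim_duration_s + config$isi_s) +
    config$lead_in_s
}
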
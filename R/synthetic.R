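#' Evoked-potential template
#'
#' Damped oscillation used as the stereotyped stimulus-evoked LFP waveform:
#' `amp * exp(-t / decay) * sin(2 pi f t)`, starting `evoked_onset_s` after
#' stimulus onset. The shape is a configurable artifact of the generator, not
#' a biophysical claim; only its gain scaling carries the planted structure.
#'
#' @param config A [session_config()].
#' @return Numeric vector sampled at `config$fs_lfp`.
#' @export
evoked_template <- function(config) {
  n <- round(config$evoked_dur_s * config$fs_lfp)
  t <- (seq_len(n) - 1) / config$fs_lfp
  config$evoked_amp_uv * exp(-t / config$evoked_decay_s) *
    sin(2 * pi * config$evoked_freq_hz * t)
}

# 1/f ("pink") noise via spectral shaping, seen through a first-order
# high-pass at f_hp (the AC coupling of an extracellular amplifier, which
# keeps sub-hertz drift from dominating the record); unit variance.
make_pink <- function(n, fs, f_hp = 1) {
  if (n < 4) return(stats::rnorm(n))
  m <- stats::nextn(n)  # pad to a highly composite length for the FFT
  w <- stats::rnorm(m)
  k <- seq_len(m - 1)
  f <- c(Inf, pmin(k, m - k)) * fs / m
  shape <- (f / sqrt(f^2 + f_hp^2)) / sqrt(f)
  shape[1] <- 0
  x <- Re(stats::fft(stats::fft(w) * shape, inverse = TRUE))[seq_len(n)] / m
  x / stats::sd(x)
}

make_noise <- function(n, sd_uv, pink_frac, fs, f_hp = 1) {
  if (sd_uv == 0) return(numeric(n))
  out <- numeric(n)
  if (pink_frac < 1) out <- out + sqrt(1 - pink_frac) * stats::rnorm(n)
  if (pink_frac > 0) out <- out + sqrt(pink_frac) * make_pink(n, fs, f_hp)
  sd_uv * out
}

# Reflect a free random walk into [-bound, bound].
reflect_into <- function(x, bound) {
  if (!is.finite(bound)) return(x)
  y <- (x + bound) %% (4 * bound)
  ifelse(y > 2 * bound, 4 * bound - y, y) - bound
}

# Raised-cosine excursion of given amplitude/duration added at onset times.
add_pulses <- function(theta, times, onsets, amp, dur) {
  for (t0 in onsets) {
    sel <- which(times >= t0 & times <= t0 + dur)
    if (length(sel))
      theta[sel] <- theta[sel] + amp * sin(pi * (times[sel] - t0) / dur)^2
  }
  theta
}

rot2 <- function(rho_deg) {
  r <- rho_deg * pi / 180
  matrix(c(cos(r), sin(r), -sin(r), cos(r)), 2, 2)
}

# Per-trial evoked gain under position-specific adaptation.
# Standards decay with the count of prior presentations at their adaptation
# key; deviants keep gain_deviant. In the retinotopic regime the key couples
# the screen position with a head-angle bin, so a newly assumed head angle
# resets adaptation (the structure first-view detection must expose).
schedule_gains <- function(schedule, theta_at_onset, config, bias = NULL) {
  n <- nrow(schedule)
  key <- as.character(schedule$pos_index)
  if (isTRUE(config$retinotopic)) {
    bin <- floor((theta_at_onset + config$head_angle_bound_deg) /
                   config$angle_bin_deg)
    key <- paste(key, bin, sep = "/")
  }
  seen <- new.env(parent = emptyenv())
  gain <- numeric(n)
  for (i in seq_len(n)) {
    k <- key[i]
    n_prior <- if (is.null(seen[[k]])) 0L else seen[[k]]
    if (schedule$condition[i] == "deviant") {
      gain[i] <- config$gain_deviant
    } else {
      decay <- if (is.finite(config$adaptation_tau_trials)) {
        if (config$adaptation_tau_trials == 0) as.numeric(n_prior == 0)
        else exp(-n_prior / config$adaptation_tau_trials)
      } else 1
      gain[i] <- config$gain_standard +
        (config$gain_standard_initial - config$gain_standard) * decay
    }
    if (!is.null(bias)) gain[i] <- gain[i] * bias[schedule$pos_index[i]]
    seen[[k]] <- n_prior + 1L
  }
  gain
}

build_trial_log <- function(schedule, config) {
  n <- nrow(schedule)
  onset <- config$lead_in_s +
    (seq_len(n) - 1) * (config$stim_duration_s + config$isi_s)
  pos <- config$grid$positions[schedule$pos_index, , drop = FALSE]
  log <- data.frame(
    trial_index = seq_len(n) - 1L,
    onset_s = onset,
    offset_s = onset + config$stim_duration_s,
    condition = schedule$condition,
    pos_col = pos$col,
    pos_row = pos$row,
    stringsAsFactors = FALSE
  )
  derive_trial_flags(log)
}

head_stream <- function(times, log, config) {
  n <- length(times)
  eps <- stats::rnorm(n, sd = config$head_walk_sd_deg)
  eps[1] <- 0
  if (config$still_trial_frac > 0) {
    n_still <- round(config$still_trial_frac * nrow(log))
    still <- sample(nrow(log), n_still)
    for (i in still) {
      sel <- times >= log$onset_s[i] & times <= log$onset_s[i] + 0.4
      eps[sel] <- 0
    }
  }
  reflect_into(cumsum(eps), config$head_angle_bound_deg)
}

# Pick movement-epoch onsets inside inter-stimulus intervals, at most one per
# interval, leaving the post-offset response exclusion zone (80-480 ms) and
# the next onset clear.
pick_move_onsets <- function(log, config, rate_per_min, dur) {
  if (rate_per_min <= 0) return(numeric(0))
  lo <- log$offset_s + 1.0
  hi <- c(log$onset_s[-1], log$offset_s[nrow(log)] + config$isi_s) - dur - 0.6
  ok <- which(hi > lo)
  n_mv <- min(length(ok), round(rate_per_min * session_duration(config) / 60))
  if (n_mv == 0) return(numeric(0))
  pick <- sort(sample(ok, n_mv))
  sort(lo[pick] + stats::runif(n_mv) * (hi[pick] - lo[pick]))
}

keypoint_frame <- function(frame, time_s, point_name, x, y, likelihood) {
  data.frame(frame = frame, time_s = time_s, point_name = point_name,
             x_px = x, y_px = y, likelihood = likelihood,
             stringsAsFactors = FALSE)
}

head_keypoints_from_theta <- function(times, theta_deg, config) {
  th <- theta_deg * pi / 180
  n <- length(times)
  dx <- (config$head_len_px / 2) * cos(th)
  dy <- (config$head_len_px / 2) * sin(th)
  jit <- function() if (config$head_noise_px > 0)
    stats::rnorm(n, sd = config$head_noise_px) else 0
  rbind(
    keypoint_frame(seq_len(n) - 1L, times, "rostral",
                   config$head_center_px[1] + dx + jit(),
                   config$head_center_px[2] + dy + jit(), 1),
    keypoint_frame(seq_len(n) - 1L, times, "caudal",
                   config$head_center_px[1] - dx + jit(),
                   config$head_center_px[2] - dy + jit(), 1)
  )
}

eye_stream <- function(times, log, config) {
  n <- length(times)
  walk <- function() {
    e <- stats::rnorm(n, sd = config$eye_walk_sd_deg)
    e[1] <- 0
    90 + reflect_into(cumsum(e), 30)
  }
  psi_x <- walk()
  psi_y <- walk()
  onsets <- pick_move_onsets(log, config, config$eye_move_rate_per_min,
                             config$eye_move_dur_s)
  psi_x <- 90 + reflect_into(
    add_pulses(psi_x - 90, times, onsets, config$eye_move_amp_deg,
               config$eye_move_dur_s), 30)
  list(psi_x = psi_x, psi_y = psi_y, move_onsets_s = onsets)
}

# Pupil-outline keypoints consistent with true eye angles: the pupil centre
# sits at socket_centre + radius * cos(psi) on each axis (the inverse of the
# arccosine gaze model), and outline points sample a small tilted ellipse
# around that centre.
eye_keypoints_from_psi <- function(times, psi_x, psi_y, config) {
  n <- length(times)
  cx <- config$socket_center_px[1] +
    config$socket_radius_px * cos(psi_x * pi / 180)
  cy <- config$socket_center_px[2] +
    config$socket_radius_px * cos(psi_y * pi / 180)
  K <- config$n_pupil_points
  tilt <- config$pupil_tilt_deg * pi / 180
  a <- config$pupil_axes_px[1]; b <- config$pupil_axes_px[2]
  out <- vector("list", K)
  for (k in seq_len(K)) {
    ang <- 2 * pi * (k - 1) / K + 0.3
    ex <- a * cos(ang) * cos(tilt) - b * sin(ang) * sin(tilt)
    ey <- a * cos(ang) * sin(tilt) + b * sin(ang) * cos(tilt)
    jx <- if (config$eye_noise_px > 0) stats::rnorm(n, sd = config$eye_noise_px) else 0
    jy <- if (config$eye_noise_px > 0) stats::rnorm(n, sd = config$eye_noise_px) else 0
    out[[k]] <- keypoint_frame(seq_len(n) - 1L, times,
                               sprintf("pupil_%d", k),
                               cx + ex + jx, cy + ey + jy, 1)
  }
  do.call(rbind, out)
}

socket_annotation <- function(config, n_points = 12L) {
  ang <- 2 * pi * (seq_len(n_points) - 1) / n_points
  data.frame(
    point_name = sprintf("socket_%d", seq_len(n_points)),
    x_px = config$socket_center_px[1] + config$socket_radius_px * cos(ang),
    y_px = config$socket_center_px[2] + config$socket_radius_px * sin(ang),
    stringsAsFactors = FALSE
  )
}

inject_lowlik <- function(kp, frac) {
  if (frac <= 0) return(kp)
  sel <- sample(nrow(kp), round(frac * nrow(kp)))
  kp$likelihood[sel] <- 0.3
  kp
}

generate_session_core <- function(config, schedule, bias = NULL) {
  set.seed(config$seed)
  log <- build_trial_log(schedule, config)
  dur <- config$lead_in_s + nrow(log) * (config$stim_duration_s + config$isi_s) +
    config$lead_in_s

  # --- head stream -------------------------------------------------------
  t_head <- seq(0, dur, by = 1 / config$fs_video_head)
  theta <- head_stream(t_head, log, config)
  head_moves <- pick_move_onsets(log, config, config$move_rate_per_min,
                                 config$move_dur_s)
  theta <- add_pulses(theta, t_head, head_moves, config$move_amp_deg,
                      config$move_dur_s)
  head_kp <- inject_lowlik(head_keypoints_from_theta(t_head, theta, config),
                           config$lowlik_frac)

  # --- per-trial gains (need head angle at onset for the retinotopic key) -
  th_at_onset <- theta[pmax(1L, findInterval(log$onset_s, t_head))]
  gain <- schedule_gains(schedule, th_at_onset, config, bias)

  # --- LFP ---------------------------------------------------------------
  n_samp <- round(dur * config$fs_lfp)
  tmpl <- evoked_template(config)
  evoked <- numeric(n_samp)
  starts <- floor((log$onset_s + config$evoked_onset_s) * config$fs_lfp) + 1L
  for (i in seq_len(nrow(log))) {
    idx <- starts[i]:min(starts[i] + length(tmpl) - 1L, n_samp)
    evoked[idx] <- evoked[idx] + gain[i] * tmpl[seq_along(idx)]
  }
  if (config$movement_lfp_gain > 0 && length(head_moves)) {
    mstarts <- floor(head_moves * config$fs_lfp) + 1L
    for (s in mstarts) {
      idx <- s:min(s + length(tmpl) - 1L, n_samp)
      evoked[idx] <- evoked[idx] + config$movement_lfp_gain * tmpl[seq_along(idx)]
    }
  }
  voltage <- matrix(0, nrow = config$n_channels, ncol = n_samp)
  for (ch in seq_len(config$n_channels)) {
    voltage[ch, ] <- config$channel_gains[ch] * evoked +
      make_noise(n_samp, config$noise_sd_uv, config$noise_pink_frac,
                 config$fs_lfp, config$noise_highpass_hz)
  }
  rec <- list(voltage = voltage, fs = config$fs_lfp, t0 = 0)
  class(rec) <- "continuous_recording"

  # --- eye stream --------------------------------------------------------
  eye_kp <- NULL; eye_truth <- NULL; eye_moves <- numeric(0)
  if (isTRUE(config$include_eye)) {
    t_eye <- seq(0, dur, by = 1 / config$fs_video_eye)
    es <- eye_stream(t_eye, log, config)
    eye_moves <- es$move_onsets_s
    eye_kp <- inject_lowlik(
      eye_keypoints_from_psi(t_eye, es$psi_x, es$psi_y, config),
      config$lowlik_frac)
    phi <- rot2(config$rho_deg) %*% rbind(es$psi_x, es$psi_y)
    eye_truth <- data.frame(
      frame = seq_along(t_eye) - 1L, time_s = t_eye,
      psi_x = es$psi_x, psi_y = es$psi_y,
      phi_x = phi[1, ] - mean(phi[1, ]),
      phi_y = phi[2, ] - mean(phi[2, ])
    )
  }

  truth <- list(
    gain = gain,
    head = data.frame(frame = seq_along(t_head) - 1L, time_s = t_head,
                      theta_deg = theta),
    eye = eye_truth,
    head_move_onsets_s = head_moves,
    eye_move_onsets_s = eye_moves
  )

  session <- list(rec = rec, log = log, head = head_kp, eye = eye_kp,
                  socket = socket_annotation(config), truth = truth,
                  config = config)
  class(session) <- "oddball_session"
  session
}

#' Generate a synthetic oddball session
#'
#' Produces a complete session — continuous LFP, trial log, top-camera head
#' keypoints, eye-camera pupil keypoints and the planted ground truth — with
#' the statistical structure the analysis pipeline assumes: a frequent
#' standard and a rare deviant screen position (deviant fraction
#' `deviant_prob`), position-specific adaptation of the evoked gain, constant
#' high deviant gain, oscillatory evoked waveforms on background noise, a
#' bounded head-angle random walk and pupil keypoints consistent with the
#' true eye angles. Deviants are scheduled after the first ten trials. The
#' seed in `config` fully determines the output.
#'
#' @param config A [session_config()].
#' @return An `oddball_session` list: `rec` (continuous recording), `log`
#'   (trial log with derived flags), `head`/`eye` (keypoint tables), `socket`
#'   (socket-outline annotation), `truth` (planted ground truth; never used
#'   by the analysis stages), `config`.
#' @export
generate_oddball_session <- function(config) {
  validate_session_config(config)
  set.seed(config$seed)
  n <- config$n_trials
  n_dev <- round(n * config$deviant_prob)
  eligible <- if (n > 10) 11:n else seq_len(n)
  if (n_dev > length(eligible))
    stop("invalid session_config: field 'deviant_prob' leaves no room for deviants after trial 10")
  dev_at <- sample(eligible, n_dev)
  condition <- rep("standard", n)
  condition[dev_at] <- "deviant"
  pos_index <- ifelse(condition == "deviant", config$grid$deviant,
                      config$grid$standard)
  schedule <- data.frame(condition = condition, pos_index = pos_index,
                         stringsAsFactors = FALSE)
  generate_session_core(config, schedule)
}

#' Generate a synthetic spatial-control session
#'
#' Control sessions present every grid position equally often (default 20
#' repeats each) in uniformly random order, with no oddball structure. An
#' optional per-position gain bias can be planted to emulate genuine spatial
#' response preferences, which downstream control projection must expose.
#'
#' @param config A [session_config()]; `n_trials` is ignored (the schedule is
#'   `n_positions * control_repeats` trials).
#' @param position_bias Numeric vector, one multiplicative gain per grid
#'   position (default all 1).
#' @param control_repeats Presentations per position (default 20).
#' @return An `oddball_session` list, as [generate_oddball_session()].
#' @export
generate_control_session <- function(config, position_bias = NULL,
                                     control_repeats = 20L) {
  validate_session_config(config)
  n_pos <- nrow(config$grid$positions)
  if (is.null(position_bias)) position_bias <- rep(1, n_pos)
  if (length(position_bias) != n_pos)
    stop("position_bias must have one entry per grid position")
  set.seed(config$seed)
  pos_index <- sample(rep(seq_len(n_pos), each = control_repeats))
  schedule <- data.frame(condition = "standard", pos_index = pos_index,
                         stringsAsFactors = FALSE)
  cfg <- config
  cfg$n_trials <- length(pos_index)
  generate_session_core(cfg, schedule, bias = position_bias)
}

#' @export
print.oddball_session <- function(x, ...) {
  cat("<oddball_session>\n")
  cat(sprintf("  %d trials (%d deviant), %.0f s at %g Hz, %d channel(s)\n",
              nrow(x$log), sum(x$log$condition == "deviant"),
              ncol(x$rec$voltage) / x$rec$fs, x$rec$fs,
              nrow(x$rec$voltage)))
  cat(sprintf("  head frames: %d; eye stream: %s\n",
              length(unique(x$head$frame)),
              if (is.null(x$eye)) "absent" else "present"))
  invisible(x)
}
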
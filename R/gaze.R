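wrap_deg <- function(x) ((x + 180) %% 360) - 180

#' Circular mean of angles in degrees
#' @param x Angles, degrees. NAs are dropped.
#' @return Mean angle in (-180, 180], or NA if no finite input.
#' @export
circ_mean_deg <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(NA_real_)
  r <- x * pi / 180
  atan2(mean(sin(r)), mean(cos(r))) * 180 / pi
}

#' Extract the track of one named keypoint
#' @param kp Keypoint table (`frame`, `time_s`, `point_name`, `x_px`,
#'   `y_px`, `likelihood`).
#' @param point_name Point to extract.
#' @param likelihood_min Confidence threshold (default 0.9).
#' @return data.frame `time_s`, `x`, `y`, ordered by time.
#' @export
point_track <- function(kp, point_name, likelihood_min = 0.9) {
  kp <- filter_keypoints(kp[kp$point_name == point_name, , drop = FALSE],
                         likelihood_min)
  out <- data.frame(time_s = kp$time_s, x = kp$x_px, y = kp$y_px)
  out[order(out$time_s), , drop = FALSE]
}

# Per-frame head bearing (degrees) from the caudal -> rostral keypoint pair.
# Frames missing either point (below the likelihood cut) are dropped.
head_bearing_frames <- function(head_kp, likelihood_min = 0.9) {
  r <- point_track(head_kp, "rostral", likelihood_min)
  c_ <- point_track(head_kp, "caudal", likelihood_min)
  common <- intersect(r$time_s, c_$time_s)
  r <- r[match(common, r$time_s), ]
  c_ <- c_[match(common, c_$time_s), ]
  data.frame(time_s = common,
             bearing_deg = atan2(r$y - c_$y, r$x - c_$x) * 180 / pi)
}

#' Per-trial head angle from top-camera keypoints
#'
#' The head direction of each frame is the bearing of the caudal-to-rostral
#' keypoint vector; the per-trial angle is the circular mean over frames in
#' the window (default onset to 400 ms post-stimulus). Zero is defined as
#' the session's average angle across trials, positive angles are turns to
#' one side. Trials without a valid frame are marked missing (NA) with a
#' warning and excluded from all angle analyses.
#'
#' @param head_kp Head keypoint table.
#' @param log Trial log.
#' @param window Averaging window relative to onset, seconds (default
#'   `c(0, 0.4)`).
#' @param likelihood_min Keypoint confidence threshold.
#' @return data.frame `trial_index`, `theta_deg` (mean-zeroed), `n_frames`.
#' @export
head_angle_per_trial <- function(head_kp, log, window = c(0, 0.4),
                                 likelihood_min = 0.9) {
  fr <- head_bearing_frames(head_kp, likelihood_min)
  raw <- vapply(seq_len(nrow(log)), function(i) {
    sel <- fr$time_s >= log$onset_s[i] + window[1] &
      fr$time_s <= log$onset_s[i] + window[2]
    circ_mean_deg(fr$bearing_deg[sel])
  }, numeric(1))
  n_fr <- vapply(seq_len(nrow(log)), function(i)
    sum(fr$time_s >= log$onset_s[i] + window[1] &
          fr$time_s <= log$onset_s[i] + window[2]), numeric(1))
  if (anyNA(raw))
    warning(sum(is.na(raw)), " trial(s) had no valid head frames and were marked missing")
  theta <- wrap_deg(raw - circ_mean_deg(raw))
  data.frame(trial_index = log$trial_index, theta_deg = theta,
             n_frames = as.integer(n_fr))
}

#' Classify head angles into left / right / neither
#'
#' Strict thresholds around the session mean: `left` when theta < -15
#' degrees, `right` when theta > 15 degrees, otherwise `neither` (so +/-15
#' exactly is `neither`). This keeps the left and right groups composed of
#' genuinely different viewing angles.
#'
#' @param theta_deg Mean-zeroed head angles, degrees.
#' @param threshold_deg Split threshold (default 15).
#' @return Character vector in `{"left","right","neither"}` (NA preserved).
#' @export
classify_left_right <- function(theta_deg, threshold_deg = 15) {
  out <- rep(NA_character_, length(theta_deg))
  ok <- is.finite(theta_deg)
  out[ok] <- ifelse(theta_deg[ok] < -threshold_deg, "left",
                    ifelse(theta_deg[ok] > threshold_deg, "right", "neither"))
  out
}

#' Flag trials viewed from a new head angle
#'
#' A trial is a "first view" when its head angle lies at least `min_dist`
#' degrees from the angle of every previous valid trial (a row-wise minimum
#' over the lower triangle of the trial-angle distance matrix). The first
#' valid trial is flagged by convention (it has no predecessors). Trials
#' with a missing angle are never flagged and never enter the comparison
#' set.
#'
#' @param theta_deg Per-trial angles ordered by trial index.
#' @param min_dist_deg Distance threshold, degrees (default 5).
#' @return Logical flags (FALSE for missing-angle trials).
#' @export
detect_first_view <- function(theta_deg, min_dist_deg = 5) {
  n <- length(theta_deg)
  flags <- logical(n)
  seen <- numeric(0)
  for (i in seq_len(n)) {
    th <- theta_deg[i]
    if (!is.finite(th)) next
    flags[i] <- !length(seen) || min(abs(th - seen)) >= min_dist_deg
    seen <- c(seen, th)
  }
  flags
}

#' Least-squares circle fit (Kasa)
#' @param x,y Outline coordinates (>= 3 non-collinear points).
#' @return List `center` (length 2), `radius`.
#' @export
fit_circle <- function(x, y) {
  if (length(x) < 3) stop("circle fit needs at least 3 points")
  A <- cbind(2 * x, 2 * y, 1)
  b <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, b), error = function(e)
    stop("degenerate circle fit: collinear points"))
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!isTRUE(r2 > 0)) stop("degenerate circle fit")
  list(center = c(sol[1], sol[2]), radius = sqrt(r2))
}

#' Direct least-squares ellipse fit (Halir-Flusser)
#'
#' Numerically stable variant of the direct conic fit with the ellipse
#' constraint `4*a*c - b^2 = 1`; used to locate the pupil centre from
#' tracked outline points.
#'
#' @param x,y Outline coordinates (>= 5 points in general position).
#' @return List `center` (length 2), `conic` (coefficients a..f of
#'   `ax^2 + bxy + cy^2 + dx + ey + f = 0`).
#' @export
fit_ellipse <- function(x, y) {
  if (length(x) < 5) stop("ellipse fit needs at least 5 points")
  mx <- mean(x); my <- mean(y)
  xs <- x - mx; ys <- y - my
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T_ <- tryCatch(-solve(S3, t(S2)), error = function(e)
    stop("degenerate ellipse fit: points are collinear or coincident"))
  M <- S1 + S2 %*% T_
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- eigen(M)
  cond <- 4 * Re(ev$vectors[1, ]) * Re(ev$vectors[3, ]) - Re(ev$vectors[2, ])^2
  k <- which(cond > 0)
  if (!length(k)) stop("degenerate ellipse fit: no elliptical solution")
  a1 <- Re(ev$vectors[, k[1]])
  a2 <- as.numeric(T_ %*% a1)
  co <- c(a1, a2)  # a, b, c, d, e, f in centred coordinates
  ctr_c <- solve(matrix(c(2 * co[1], co[2], co[2], 2 * co[3]), 2, 2),
                 -co[4:5])
  list(center = c(ctr_c[1] + mx, ctr_c[2] + my), conic = co)
}

#' Per-frame eye angles from pupil and socket outlines
#'
#' For each frame an ellipse is fitted to the tracked pupil-outline points
#' and its centre taken as the pupil position; the manually annotated socket
#' outline is fitted once with a circle. With the socket centre as origin,
#' the raw gaze angles follow the arccosine model
#' `psi_k = arccos(k / radius)` for k in {x, y} (the argument is clipped to
#' \[-1, 1\]; a centre outside the socket by more than `clip_tol` of the
#' radius raises a warning before clipping). The vector `(psi_x, psi_y)` is
#' rotated by the visual-streak angle `rho` — aligning the eye's horizontal
#' with the video frame — and the session mean is subtracted, giving `phi`
#' relative to the mean over all eye positions.
#'
#' @param eye_kp Eye keypoint table (points named `pupil_*`).
#' @param socket Socket annotation (`x_px`, `y_px`).
#' @param rho_deg Visual-streak angle, degrees.
#' @param likelihood_min Keypoint confidence threshold.
#' @param clip_tol Tolerated relative overshoot of `|coord|/radius` beyond 1
#'   before warning (default 0.05).
#' @return data.frame per frame: `frame`, `time_s`, `pupil_x`, `pupil_y`,
#'   `psi_x`, `psi_y` (degrees, in \[0, 180\]), `phi_x`, `phi_y` (degrees,
#'   mean-subtracted). Frames with fewer than 5 valid pupil points carry NA.
#' @export
eye_angle <- function(eye_kp, socket, rho_deg, likelihood_min = 0.9,
                      clip_tol = 0.05) {
  soc <- fit_circle(socket$x_px, socket$y_px)
  kp <- filter_keypoints(eye_kp[grepl("^pupil", eye_kp$point_name), ,
                                drop = FALSE], likelihood_min)
  frames <- sort(unique(eye_kp$frame))
  times <- eye_kp$time_s[match(frames, eye_kp$frame)]
  by_frame <- split(kp[, c("x_px", "y_px")], factor(kp$frame, levels = frames))
  centers <- t(vapply(by_frame, function(d) {
    if (nrow(d) < 5) return(c(NA_real_, NA_real_))
    fit_ellipse(d$x_px, d$y_px)$center
  }, numeric(2)))
  px <- centers[, 1] - soc$center[1]
  py <- centers[, 2] - soc$center[2]
  ratio_x <- px / soc$radius
  ratio_y <- py / soc$radius
  over <- pmax(abs(ratio_x), abs(ratio_y), na.rm = FALSE)
  if (any(over > 1 + clip_tol, na.rm = TRUE))
    warning(sum(over > 1 + clip_tol, na.rm = TRUE),
            " frame(s) place the pupil centre outside the socket beyond tolerance; clipped")
  psi_x <- acos(pmin(pmax(ratio_x, -1), 1)) * 180 / pi
  psi_y <- acos(pmin(pmax(ratio_y, -1), 1)) * 180 / pi
  phi <- rot2(rho_deg) %*% rbind(psi_x, psi_y)
  data.frame(frame = frames, time_s = times,
             pupil_x = centers[, 1], pupil_y = centers[, 2],
             psi_x = psi_x, psi_y = psi_y,
             phi_x = phi[1, ] - mean(phi[1, ], na.rm = TRUE),
             phi_y = phi[2, ] - mean(phi[2, ], na.rm = TRUE),
             row.names = NULL)
}

#' Per-trial eye angle
#'
#' Averages the streak-rotated, mean-subtracted eye angles over the frames
#' of each trial window (default onset to 400 ms, matching the head-angle
#' window).
#'
#' @param eye_tab Output of [eye_angle()].
#' @param log Trial log.
#' @param window Window relative to onset, seconds.
#' @return data.frame `trial_index`, `phi_x`, `phi_y`, `n_frames`.
#' @export
eye_angle_per_trial <- function(eye_tab, log, window = c(0, 0.4)) {
  out <- lapply(seq_len(nrow(log)), function(i) {
    sel <- eye_tab$time_s >= log$onset_s[i] + window[1] &
      eye_tab$time_s <= log$onset_s[i] + window[2] &
      is.finite(eye_tab$phi_x)
    data.frame(trial_index = log$trial_index[i],
               phi_x = if (any(sel)) mean(eye_tab$phi_x[sel]) else NA_real_,
               phi_y = if (any(sel)) mean(eye_tab$phi_y[sel]) else NA_real_,
               n_frames = sum(sel))
  })
  do.call(rbind, out)
}

#' Viewing angle as the linear head + eye sum
#'
#' @param theta_deg Per-trial head angle, degrees.
#' @param phi_x_deg Per-trial horizontal eye angle, degrees.
#' @return `theta + phi_x`; NA when either component is missing (such
#'   trials are excluded from viewing-angle analyses).
#' @export
viewing_angle <- function(theta_deg, phi_x_deg) theta_deg + phi_x_deg

#' Uniform speed trace of a tracked point
#'
#' Frame-to-frame displacement divided by the frame interval, assigned to
#' the later frame's timestamp.
#'
#' @param track data.frame `time_s`, `x`, `y` (see [point_track()]).
#' @return data.frame `time_s`, `speed` (px/s), with attribute `fs`.
#' @export
speed_trace <- function(track) {
  n <- nrow(track)
  if (n < 2) stop("speed trace needs at least 2 frames")
  dt <- diff(track$time_s)
  sp <- sqrt(diff(track$x)^2 + diff(track$y)^2) / dt
  out <- data.frame(time_s = track$time_s[-1], speed = sp)
  attr(out, "fs") <- 1 / stats::median(dt)
  out
}

#' Per-trial movement speed following stimulation
#'
#' Mean frame-to-frame speed of a tracked point (nose keypoint for the
#' head, pupil centre for the eye) over 80--480 ms after stimulus onset.
#'
#' @param track data.frame `time_s`, `x`, `y`.
#' @param log Trial log.
#' @param window Window relative to onset, seconds (default
#'   `c(0.080, 0.480)`).
#' @return data.frame `trial_index`, `speed` (px/s; NA when fewer than two
#'   frames fall in the window).
#' @export
trial_speeds <- function(track, log, window = c(0.080, 0.480)) {
  st <- speed_trace(track)
  sp <- vapply(seq_len(nrow(log)), function(i) {
    sel <- st$time_s > log$onset_s[i] + window[1] &
      st$time_s <= log$onset_s[i] + window[2]
    if (sum(sel) < 1) NA_real_ else mean(st$speed[sel])
  }, numeric(1))
  n_fr <- vapply(seq_len(nrow(log)), function(i)
    sum(track$time_s >= log$onset_s[i] + window[1] &
          track$time_s <= log$onset_s[i] + window[2]), numeric(1))
  sp[n_fr < 2] <- NA_real_
  data.frame(trial_index = log$trial_index, speed = sp)
}

#' Assemble the per-trial gaze table
#'
#' Runs head-angle extraction, left/right classification, first-view
#' detection, optional eye-angle estimation and viewing-angle summation,
#' plus post-stimulus head/eye speeds, into a single per-trial table.
#'
#' @param session An `oddball_session` (eye stream optional).
#' @param likelihood_min Keypoint confidence threshold.
#' @param angle_threshold_deg Left/right split threshold (default 15).
#' @param first_view_min_dist_deg First-view distance threshold (default 5).
#' @return A `gaze_table` data.frame: `trial_index`, `theta_deg`,
#'   `angle_group`, `is_first_view`, `phi_x`, `phi_y`, `viewing_deg`,
#'   `head_speed`, `eye_speed`.
#' @export
build_gaze_table <- function(session, likelihood_min = 0.9,
                             angle_threshold_deg = 15,
                             first_view_min_dist_deg = 5) {
  log <- session$log
  ha <- head_angle_per_trial(session$head, log, likelihood_min = likelihood_min)
  gz <- data.frame(trial_index = log$trial_index,
                   theta_deg = ha$theta_deg)
  gz$angle_group <- classify_left_right(gz$theta_deg, angle_threshold_deg)
  gz$is_first_view <- detect_first_view(gz$theta_deg, first_view_min_dist_deg)
  nose <- point_track(session$head, "rostral", likelihood_min)
  gz$head_speed <- trial_speeds(nose, log)$speed
  gz$phi_x <- NA_real_; gz$phi_y <- NA_real_; gz$eye_speed <- NA_real_
  eye_tab <- NULL
  if (!is.null(session$eye)) {
    eye_tab <- eye_angle(session$eye, session$socket,
                         session$config$rho_deg, likelihood_min)
    ea <- eye_angle_per_trial(eye_tab, log)
    gz$phi_x <- ea$phi_x; gz$phi_y <- ea$phi_y
    pc <- data.frame(time_s = eye_tab$time_s, x = eye_tab$pupil_x,
                     y = eye_tab$pupil_y)
    pc <- pc[stats::complete.cases(pc), ]
    gz$eye_speed <- trial_speeds(pc, log)$speed
  }
  gz$viewing_deg <- viewing_angle(gz$theta_deg, gz$phi_x)
  attr(gz, "eye_frames") <- eye_tab
  class(gz) <- c("gaze_table", "data.frame")
  gz
}
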
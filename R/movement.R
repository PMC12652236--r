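#' Detect movement onsets on a speed trace
#'
#' Isolated peaks of the (uniformly sampled) head or eye speed trace are
#' detected with a peak finder; a peak qualifies when its height reaches the
#' trace mean plus `k_sd` standard deviations and it is separated from the
#' next peak by at least `min_separation_s`. Peaks falling inside the
#' stimulus-response exclusion zones — 80 to 480 ms after any stimulus onset
#' or offset — are discarded, so stimulus-evoked movements never count as
#' spontaneous movement epochs.
#'
#' @param st Speed trace from [speed_trace()].
#' @param log Trial log.
#' @param k_sd Height threshold in SDs above the mean (default 2).
#' @param min_separation_s Minimum inter-peak separation, seconds (default 1).
#' @param exclusion_window_s Exclusion zone after onsets/offsets, seconds
#'   (default `c(0.080, 0.480)`).
#' @return Numeric vector of onset times, seconds.
#' @export
detect_movement_onsets <- function(st, log, k_sd = 2, min_separation_s = 1,
                                   exclusion_window_s = c(0.080, 0.480)) {
  if (!nrow(st)) stop("empty speed trace")
  fs <- attr(st, "fs")
  thr <- mean(st$speed) + k_sd * stats::sd(st$speed)
  pk <- pracma::findpeaks(st$speed, minpeakheight = thr,
                          minpeakdistance = max(1L, round(min_separation_s * fs)))
  if (is.null(pk)) return(numeric(0))
  times <- st$time_s[pk[, 2]]
  edges <- c(log$onset_s, log$offset_s)
  excluded <- vapply(times, function(t0)
    any(t0 >= edges + exclusion_window_s[1] &
          t0 <= edges + exclusion_window_s[2]), logical(1))
  sort(times[!excluded])
}

#' Mean absolute LFP over a window
#'
#' The activity magnitude used for movement-vs-stimulus comparisons: the
#' average of |voltage| over the samples of `window` on one channel.
#'
#' @param rec Continuous recording.
#' @param window `c(start_s, end_s)` on the session clock (half-open).
#' @param channel 1-based channel index.
#' @return Magnitude in microvolt.
#' @export
activity_magnitude <- function(rec, window, channel = 1L) {
  s0 <- floor((window[1] - rec$t0) * rec$fs)
  n <- round((window[2] - window[1]) * rec$fs)
  if (n < 1) stop("empty window")
  if (s0 < 0 || s0 + n > ncol(rec$voltage))
    stop("window outside recording")
  mean(abs(rec$voltage[channel, (s0 + 1):(s0 + n)]))
}

# Sliding-max activity magnitude: 200-ms windows advanced in 50-ms steps
# across [start_s, start_s + span_s]; ties broken toward the earliest
# window. Returns the maximum, the chosen window and all candidates.
sliding_max_magnitude <- function(rec, start_s, span_s, channel,
                                  win_s = 0.2, step_s = 0.05) {
  starts <- seq(start_s, start_s + span_s - win_s, by = step_s)
  mags <- vapply(starts, function(s)
    activity_magnitude(rec, c(s, s + win_s), channel), numeric(1))
  k <- which.max(mags)
  list(magnitude = mags[k], window = c(starts[k], starts[k] + win_s),
       starts = starts, magnitudes = mags)
}

# Intervals occupied by stimuli (onset to offset + post-offset response
# exclusion) as a 2-column matrix.
stimulus_intervals <- function(log, post_s = 0.48) {
  cbind(log$onset_s, log$offset_s + post_s)
}

interval_clear <- function(lo, hi, intervals, points = numeric(0)) {
  if (nrow(intervals) &&
      any(lo < intervals[, 2] & hi > intervals[, 1])) return(FALSE)
  !any(points >= lo & points <= hi)
}

#' Baseline-subtracted movement response magnitude
#'
#' Movement epochs are not time-locked to a precise event, so the response
#' magnitude is the maximum over a 200-ms window slid in 50-ms steps from
#' movement onset to 1 s after (head) or 0.5 s after (eye). The baseline is
#' obtained by applying the same sliding-max procedure to the closest
#' equally long episode containing no movement onset and no stimulus epoch,
#' searched outward in 50-ms steps alternating before/after the epoch
#' (nearer side first). The relative magnitude is response minus baseline.
#'
#' @param rec Continuous recording.
#' @param onset_s Movement onset time, seconds.
#' @param kind `"head"` (1-s span) or `"eye"` (0.5-s span).
#' @param log Trial log (for stimulus exclusion).
#' @param all_onsets All detected movement onsets (the quiet episode must
#'   contain none).
#' @param channel Channel index.
#' @param search_horizon_s Maximum distance to search for a quiet episode
#'   (default 30 s); failure returns NULL with a warning.
#' @return A `movement_epoch` list: `onset_s`, `kind`, `chosen_window`,
#'   `magnitude`, `baseline_window`, `baseline_magnitude`,
#'   `relative_magnitude` — or NULL when no quiet episode exists.
#' @export
movement_relative_magnitude <- function(rec, onset_s,
                                        kind = c("head", "eye"), log,
                                        all_onsets = onset_s, channel = 1L,
                                        search_horizon_s = 30) {
  kind <- match.arg(kind)
  span <- if (kind == "head") 1.0 else 0.5
  t_end <- rec$t0 + ncol(rec$voltage) / rec$fs
  if (onset_s < rec$t0 || onset_s + span > t_end) {
    warning(sprintf("movement at %.2f s leaves no full response span; epoch dropped",
                    onset_s))
    return(NULL)
  }
  resp <- sliding_max_magnitude(rec, onset_s, span, channel)
  stim <- stimulus_intervals(log)
  base_start <- NA_real_
  for (k in seq(0, search_horizon_s, by = 0.05)) {
    for (cand in c(onset_s - span - k, onset_s + span + k)) {
      if (cand < rec$t0 || cand + span > t_end) next
      if (interval_clear(cand, cand + span, stim, all_onsets)) {
        base_start <- cand; break
      }
    }
    if (is.finite(base_start)) break
  }
  if (!is.finite(base_start)) {
    warning(sprintf("no quiet baseline episode within %g s of movement at %.2f s; epoch dropped",
                    search_horizon_s, onset_s))
    return(NULL)
  }
  base <- sliding_max_magnitude(rec, base_start, span, channel)
  structure(list(onset_s = onset_s, kind = kind,
                 chosen_window = resp$window, magnitude = resp$magnitude,
                 baseline_window = base$window,
                 baseline_magnitude = base$magnitude,
                 relative_magnitude = resp$magnitude - base$magnitude),
            class = "movement_epoch")
}

#' Baseline-subtracted stimulus response magnitude
#'
#' For visual stimuli the 200-ms response window is time-locked: it starts
#' 80 ms after stimulus onset. The baseline is the activity magnitude of
#' the 200-ms window immediately preceding stimulus onset.
#'
#' @param rec Continuous recording.
#' @param log Trial log.
#' @param trial_index 0-based trial index.
#' @param channel Channel index.
#' @return Relative magnitude in microvolt (NA when a window falls outside
#'   the recording).
#' @export
stimulus_relative_magnitude <- function(rec, log, trial_index, channel = 1L) {
  i <- match(trial_index, log$trial_index)
  if (is.na(i)) stop("unknown trial_index ", trial_index)
  on <- log$onset_s[i]
  tryCatch(
    activity_magnitude(rec, c(on + 0.08, on + 0.28), channel) -
      activity_magnitude(rec, c(on - 0.2, on), channel),
    error = function(e) NA_real_)
}

one_sample_t_greater <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2)
    return(list(t = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE))
  if (stats::sd(x) == 0) {
    # zero variance: the t statistic is undefined; report the limiting p
    return(list(t = if (mean(x) == 0) 0 else sign(mean(x)) * Inf,
                p = if (mean(x) > 0) 0 else if (mean(x) == 0) 0.5 else 1,
                n = length(x), degenerate = TRUE))
  }
  tt <- stats::t.test(x, mu = 0, alternative = "greater")
  list(t = unname(tt$statistic), p = tt$p.value, n = length(x),
       degenerate = FALSE)
}

#' Compare stimulus-evoked and movement-evoked response sizes
#'
#' For each session the mean movement relative magnitude is subtracted from
#' the mean stimulus relative magnitude of standard and of deviant trials,
#' giving per-session differences `delta_std` and `delta_dev`; one-sided
#' one-sample t tests then ask whether each difference population exceeds
#' zero. Sessions lacking movement epochs are excluded.
#'
#' @param session_summaries List of per-session lists with elements
#'   `movement_mean`, `stim_std_mean`, `stim_dev_mean` (as produced by
#'   [run_oddball_analysis()] under `$movement`).
#' @return List: `delta_std`, `delta_dev` (per-session vectors),
#'   `t_std`, `t_dev` (one-sided t-test results), `n_sessions`.
#' @export
compare_movement_vs_stimulus <- function(session_summaries) {
  keep <- vapply(session_summaries, function(s)
    is.finite(s$movement_mean), logical(1))
  ss <- session_summaries[keep]
  if (length(ss) < 2)
    stop("need at least 2 sessions with movement epochs")
  delta_std <- vapply(ss, function(s) s$stim_std_mean - s$movement_mean,
                      numeric(1))
  delta_dev <- vapply(ss, function(s) s$stim_dev_mean - s$movement_mean,
                      numeric(1))
  list(delta_std = delta_std, delta_dev = delta_dev,
       t_std = one_sample_t_greater(delta_std),
       t_dev = one_sample_t_greater(delta_dev),
       n_sessions = length(ss))
}
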
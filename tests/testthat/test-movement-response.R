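speed_df <- function(speed, fs = 15) {
  out <- data.frame(time_s = seq_along(speed) / fs, speed = speed)
  attr(out, "fs") <- fs
  out
}

far_log <- mini_log(500, "standard")  # one trial far outside every test trace

test_that("a flat speed trace has no movement onsets", {
  expect_length(detect_movement_onsets(speed_df(rep(3, 200)), far_log), 0)
})

test_that("isolated speed bumps are detected at their peaks and stimulus-locked peaks are discarded", {
  fs <- 15
  times <- seq(1 / fs, 12, by = 1 / fs)
  set.seed(7)
  sp <- abs(rnorm(length(times), 1, 0.2))
  bump <- function(t0) 20 * exp(-(times - t0)^2 / (2 * 0.1^2))
  sp2 <- sp + bump(3) + bump(6)
  st <- speed_df(sp2, fs)
  on <- detect_movement_onsets(st, far_log)
  expect_length(on, 2)
  expect_equal(on, c(3, 6), tolerance = 1.01 / fs)
  # a bump 0.2 s after a stimulus onset falls in the 80-480 ms exclusion zone
  log2 <- mini_log(5, "standard")
  st3 <- speed_df(sp + bump(5.2), fs)
  expect_length(detect_movement_onsets(st3, log2), 0)
  # the same bump placed 0.2 s after stimulus OFFSET is excluded too
  st4 <- speed_df(sp + bump(7.2), fs)
  expect_length(detect_movement_onsets(st4, log2), 0)
  # outside the zones it is kept
  st5 <- speed_df(sp + bump(9.5), fs)
  expect_equal(detect_movement_onsets(st5, log2), 9.5, tolerance = 1.01 / fs)
})

test_that("activity magnitude is the mean absolute voltage, matching the sine closed form", {
  fs <- 2000
  rec <- mini_rec(rep(4.5, fs * 2), fs)
  expect_equal(activity_magnitude(rec, c(0.5, 1.5)), 4.5)
  expect_equal(activity_magnitude(mini_rec(rep(0, fs), fs), c(0, 0.5)), 0)
  t <- (0:(fs - 1)) / fs
  rec_sin <- mini_rec(7 * sin(2 * pi * 10 * t), fs)  # 10 whole cycles
  expect_equal(activity_magnitude(rec_sin, c(0, 1)), 2 * 7 / pi,
               tolerance = 1e-3)
  expect_error(activity_magnitude(rec, c(0.5, 0.5)), "empty window")
  expect_error(activity_magnitude(rec, c(1.5, 2.5)), "outside")
})

test_that("the sliding window enumerates 17 (head) / 7 (eye) candidates and its max dominates every candidate", {
  fs <- 2000
  set.seed(8)
  rec <- mini_rec(rnorm(fs * 10, sd = 20), fs)
  sm_head <- gazeodd:::sliding_max_magnitude(rec, 2, 1.0, 1L)
  expect_length(sm_head$starts, 17)  # (1000 - 200) / 50 + 1
  sm_eye <- gazeodd:::sliding_max_magnitude(rec, 2, 0.5, 1L)
  expect_length(sm_eye$starts, 7)    # (500 - 200) / 50 + 1
  # enumeration oracle
  brute <- vapply(sm_head$starts, function(s)
    activity_magnitude(rec, c(s, s + 0.2)), numeric(1))
  expect_equal(sm_head$magnitudes, brute)
  expect_equal(sm_head$magnitude, max(brute))
  expect_true(all(sm_head$magnitude >= brute))
  # earliest window wins ties on a flat trace
  flat <- mini_rec(rep(1, fs * 10), fs)
  expect_equal(gazeodd:::sliding_max_magnitude(flat, 2, 1.0, 1L)$window,
               c(2, 2.2))
})

test_that("a boxcar deflection after movement onset is captured by the chosen window", {
  fs <- 2000
  v <- rep(0, fs * 60)
  on <- 30
  v[(round((on + 0.3) * fs) + 1):(round((on + 0.45) * fs))] <- 12
  rec <- mini_rec(v, fs)
  ep <- movement_relative_magnitude(rec, on, "head", far_log)
  expect_true(ep$chosen_window[1] <= on + 0.3 &&
                ep$chosen_window[2] >= on + 0.45 - 0.2)
  # brute force over all candidate windows
  brute <- max(vapply(seq(on, on + 0.8, by = 0.05), function(s)
    activity_magnitude(rec, c(s, s + 0.2)), numeric(1)))
  expect_equal(ep$magnitude, brute)
  expect_equal(ep$baseline_magnitude, 0)
  expect_equal(ep$relative_magnitude, brute)
})

test_that("a flat recording has zero relative magnitude and scaling the trace scales all magnitudes", {
  fs <- 2000
  flat <- mini_rec(rep(2, fs * 60), fs)
  ep <- movement_relative_magnitude(flat, 30, "head", far_log)
  expect_equal(ep$relative_magnitude, 0)
  set.seed(9)
  v <- rnorm(fs * 60, sd = 10)
  rec <- mini_rec(v, fs)
  rec3 <- mini_rec(3 * v, fs)
  e1 <- movement_relative_magnitude(rec, 30, "head", far_log)
  e3 <- movement_relative_magnitude(rec3, 30, "head", far_log)
  expect_equal(e3$magnitude, 3 * e1$magnitude)
  expect_equal(e3$baseline_magnitude, 3 * e1$baseline_magnitude)
  expect_equal(e3$relative_magnitude, 3 * e1$relative_magnitude)
  expect_equal(e3$chosen_window, e1$chosen_window)
})

test_that("the quiet baseline episode avoids stimulus epochs and other movements", {
  fs <- 2000
  v <- rep(0, fs * 60)
  log <- mini_log(c(26, 33), c("standard", "standard"))
  # loud activity during both stimulus epochs: must not leak into baseline
  for (on in log$onset_s)
    v[(round(on * fs) + 1):(round((on + 2.48) * fs))] <- 100
  rec <- mini_rec(v, fs)
  ep <- movement_relative_magnitude(rec, 30.5, "head", log,
                                    all_onsets = c(30.5, 29.2))
  # baseline window clear of stimuli and not containing the movement at 29.2 s
  expect_equal(ep$baseline_magnitude, 0)
  expect_false(ep$baseline_window[1] <= 29.2 &&
                 ep$baseline_window[2] >= 29.2)
  expect_false(ep$baseline_window[1] < 28.48 ||
                 ep$baseline_window[2] > 33)
  # no quiet episode within the horizon: epoch dropped with a warning
  busy <- mini_rec(rep(0, fs * 8), fs)
  blog <- mini_log(c(0.5, 3, 5.5), rep("standard", 3), stim = 2)
  expect_warning(
    out <- movement_relative_magnitude(busy, 2.6, "head", blog,
                                       search_horizon_s = 1),
    "dropped")
  expect_null(out)
})

test_that("stimulus relative magnitude subtracts the 200-ms pre-onset baseline", {
  fs <- 2000
  log <- mini_log(10, "standard")
  v <- rep(3, fs * 20)  # identical pre/post: relative = 0
  expect_equal(stimulus_relative_magnitude(mini_rec(v, fs), log, 0L), 0)
  v2 <- rep(0, fs * 20)
  v2[(round(10.08 * fs) + 1):(round(10.28 * fs))] <- 9  # planted bump
  expect_equal(stimulus_relative_magnitude(mini_rec(v2, fs), log, 0L), 9,
               tolerance = 1e-9)
  expect_error(stimulus_relative_magnitude(mini_rec(v2, fs), log, 5L),
               "unknown trial")
})

test_that("movement-vs-stimulus population comparison handles degenerate difference vectors", {
  mk <- function(mv, st, dv) list(movement_mean = mv, stim_std_mean = st,
                                  stim_dev_mean = dv)
  z <- compare_movement_vs_stimulus(list(mk(1, 1, 1), mk(2, 2, 2),
                                         mk(0.5, 0.5, 0.5)))
  expect_equal(z$t_std$t, 0)
  expect_equal(z$t_std$p, 0.5)
  ones <- compare_movement_vs_stimulus(list(mk(0, 1, 1), mk(0, 1, 1),
                                            mk(0, 1, 1), mk(0, 1, 1)))
  expect_true(ones$t_std$degenerate)
  expect_equal(ones$t_std$p, 0)
  # sessions without movement epochs are excluded
  expect_error(compare_movement_vs_stimulus(list(mk(NA, 1, 1), mk(NA, 1, 1))),
               "at least 2 sessions")
  mixed <- compare_movement_vs_stimulus(list(mk(NA, 9, 9), mk(0, 1, 2),
                                             mk(0, 2, 3)))
  expect_equal(mixed$n_sessions, 2)
  expect_equal(mixed$delta_std, c(1, 2))
})
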
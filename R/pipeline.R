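stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

perm_summary <- function(x) {
  if (is.null(x)) return(NULL)
  list(observed = x$observed, statistic = x$statistic, p_value = x$p_value,
       n_permutations = x$n_permutations, n_a = x$n_a, n_b = x$n_b,
       seed = x$seed)
}

#' Run the full oddball analysis on one session
#'
#' Composes every stage of the pipeline: analysis-channel selection,
#' response-window extraction (80--580 ms, 400 Hz, artifact cut), balanced
#' repeated-PCA fit, projection of all trials, within-session permutation
#' tests (deviant, first-10, one-after-deviant, first-view, left-vs-right),
#' gaze-table construction, post-stimulus speed summaries, head--eye
#' correlation, and movement-vs-stimulus activity magnitudes. Every source
#' of randomness derives from `seed`, so the report is reproducible
#' bit-for-bit from (inputs, config, seed).
#'
#' @param session An `oddball_session` (generated or loaded).
#' @param n_perm Permutations per test (default 10000).
#' @param seed Integer master seed.
#' @param channel Channel override (default: deterministic
#'   maximal-window-variance rule, [select_channel()]).
#' @param n_per_group,n_repeats Balanced-PCA parameters (defaults 20, 100).
#' @param do_gaze,do_movement Toggle the gaze and movement stages.
#' @param likelihood_min Keypoint confidence threshold.
#' @return A `session_result` list: `channel`, `model`, `scores`, `npc1`,
#'   `tests`, `gaze`, `speeds`, `head_eye_correlation`, `movement`,
#'   `n_perm`, `seed`, `config_hash`.
#' @export
run_oddball_analysis <- function(session, n_perm = 10000L, seed = 1L,
                                 channel = NULL, n_per_group = 20L,
                                 n_repeats = 100L, do_gaze = TRUE,
                                 do_movement = TRUE,
                                 likelihood_min = 0.9) {
  rec <- session$rec
  log <- session$log
  artifact_uv <- session$config$artifact_uv %||% 900
  if (is.null(channel))
    channel <- stage("select_channel", select_channel(rec, log))
  rm_ <- stage("extract_response_matrix",
               extract_response_matrix(rec, log, channel,
                                       artifact_uv = artifact_uv))
  model <- stage("fit_balanced_pc1",
                 fit_balanced_pc1(rm_, log, n_per_group = n_per_group,
                                  n_repeats = n_repeats, seed = seed))

  gz <- NULL
  if (do_gaze && !is.null(session$head)) {
    gz <- stage("gaze_table",
                build_gaze_table(session, likelihood_min = likelihood_min))
    log <- merge(log, gz[, c("trial_index", "theta_deg", "angle_group",
                             "is_first_view")],
                 by = "trial_index", all.x = TRUE, sort = TRUE,
                 suffixes = c("_drop", ""))
    log <- log[order(log$trial_index), , drop = FALSE]
  }
  scores <- stage("project_scores", project_scores(rm_, model, log))

  tests <- list()
  tests$deviant <- stage("permutation_tests",
                         session_permutation_test(scores, "deviant",
                                                  n_perm, seed + 1L))
  tests$first10 <- session_permutation_test(scores, "first10", n_perm,
                                            seed + 2L)
  if (any(group_masks(scores)$one_after))
    tests$one_after <- session_permutation_test(scores, "one_after", n_perm,
                                                seed + 3L)
  if (!is.null(gz)) {
    mk <- group_masks(scores)
    if (any(mk$first_view) && sum(mk$standard & !mk$first_view) > sum(mk$first_view))
      tests$first_view <- session_permutation_test(scores, "first_view",
                                                   n_perm, seed + 4L)
    if (any(mk$left) && any(mk$right))
      tests$left_vs_right <- session_permutation_test(scores, "left_vs_right",
                                                      n_perm, seed + 5L)
  }

  speeds <- NULL; he_cor <- NULL
  if (!is.null(gz)) {
    std <- scores$condition == "standard"
    dev <- scores$condition == "deviant"
    sp <- gz$head_speed[match(scores$trial_index, gz$trial_index)]
    speeds <- list(head_std_mean = mean(sp[std], na.rm = TRUE),
                   head_dev_mean = mean(sp[dev], na.rm = TRUE))
    if (!is.null(session$eye)) {
      spe <- gz$eye_speed[match(scores$trial_index, gz$trial_index)]
      speeds$eye_std_mean <- mean(spe[std], na.rm = TRUE)
      speeds$eye_dev_mean <- mean(spe[dev], na.rm = TRUE)
      ok <- is.finite(gz$theta_deg) & is.finite(gz$phi_x)
      if (sum(ok) >= 3 && stats::sd(gz$theta_deg[ok]) > 0 &&
          stats::sd(gz$phi_x[ok]) > 0)
        he_cor <- pearson_correlation(gz$theta_deg[ok], gz$phi_x[ok])
    }
  }

  movement <- NULL
  if (do_movement && !is.null(session$head)) {
    movement <- stage("movement_response", {
      nose <- point_track(session$head, "rostral", likelihood_min)
      st <- speed_trace(nose)
      onsets <- detect_movement_onsets(st, log)
      epochs <- list()
      for (t0 in onsets) {
        ep <- suppressWarnings(
          movement_relative_magnitude(rec, t0, "head", log,
                                      all_onsets = onsets,
                                      channel = channel))
        if (!is.null(ep)) epochs[[length(epochs) + 1L]] <- ep
      }
      rel <- vapply(epochs, `[[`, numeric(1), "relative_magnitude")
      stim_rel <- vapply(scores$trial_index, function(ti)
        stimulus_relative_magnitude(rec, log, ti, channel), numeric(1))
      std <- scores$condition == "standard"
      dev <- scores$condition == "deviant"
      list(onsets = onsets, n_epochs = length(epochs),
           epoch_relative = rel,
           movement_mean = if (length(rel)) mean(rel) else NA_real_,
           stim_std_mean = mean(stim_rel[std], na.rm = TRUE),
           stim_dev_mean = mean(stim_rel[dev], na.rm = TRUE))
    })
  }

  res <- list(channel = channel, model = model, scores = scores,
              npc1 = npc1(scores), tests = tests, gaze = gz,
              speeds = speeds, head_eye_correlation = he_cor,
              movement = movement, n_perm = n_perm, seed = seed,
              config_hash = {
                cfg <- unclass(session$config)
                cfg$seed <- NULL  # replicate sessions share one configuration
                rlang::hash(cfg)
              })
  class(res) <- "session_result"
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.session_result <- function(x, ...) {
  cat("<session_result>\n")
  cat(sprintf("  channel %d; %d retained trials\n", x$channel,
              nrow(x$scores)))
  np <- x$npc1
  cat("  nPC1:", paste(sprintf("%s=%.2f", names(np), np), collapse = ", "),
      "\n")
  for (nm in names(x$tests))
    cat(sprintf("  %s: p = %.4g\n", nm, x$tests[[nm]]$p_value))
  invisible(x)
}

#' Aggregate session results across animals
#'
#' Collects per-session nPC1 values into a matrix and runs the
#' across-session permutation tests: each trial group against the standard
#' group (whose nPC1 is 0 by construction), the standard-vs-deviant
#' difference against the left-vs-right and first-view differences
#' (absolute difference vectors, since the sign of an angle split is
#' arbitrary), a paired t test of post-stimulus head/eye speeds, and the
#' one-sided movement-vs-stimulus population tests.
#'
#' @param results List of `session_result` objects (>= 2).
#' @param n_perm,seed Permutation parameters.
#' @return A `group_result` list: `npc1` (sessions x groups matrix),
#'   `tests`, `speed_tests`, `movement`.
#' @export
run_group_analysis <- function(results, n_perm = 10000L, seed = 1L) {
  if (length(results) < 2) stop("need at least 2 sessions")
  if (length(unique(vapply(results, `[[`, character(1), "config_hash"))) > 1)
    warning("sessions were analysed under heterogeneous configurations")
  groups <- c("standard", "deviant", "first10", "one_after", "first_view",
              "left", "right")
  np <- t(vapply(results, function(r) {
    v <- r$npc1[groups]
    names(v) <- groups
    v
  }, numeric(length(groups))))
  tests <- list()
  zero <- np[, "standard"]
  for (g in c("deviant", "first10", "one_after")) {
    v <- np[, g]
    ok <- is.finite(v)
    if (sum(ok) >= 2)
      tests[[paste0(g, "_vs_standard")]] <-
        group_permutation_test(v[ok], zero[ok], n_perm, seed)
  }
  dev_diff <- np[, "deviant"]
  lr_diff <- np[, "left"] - np[, "right"]
  fv_diff <- np[, "first_view"]
  ok <- is.finite(dev_diff) & is.finite(lr_diff)
  if (sum(ok) >= 2)
    tests$dev_diff_vs_left_right <-
      group_permutation_test(abs(dev_diff[ok]), abs(lr_diff[ok]), n_perm,
                             seed + 1L)
  ok <- is.finite(dev_diff) & is.finite(fv_diff)
  if (sum(ok) >= 2)
    tests$dev_diff_vs_first_view <-
      group_permutation_test(abs(dev_diff[ok]), abs(fv_diff[ok]), n_perm,
                             seed + 2L)

  speed_tests <- list()
  hs <- vapply(results, function(r) r$speeds$head_std_mean %||% NA_real_,
               numeric(1))
  hd <- vapply(results, function(r) r$speeds$head_dev_mean %||% NA_real_,
               numeric(1))
  ok <- is.finite(hs) & is.finite(hd)
  if (sum(ok) >= 2 && stats::sd(hd[ok] - hs[ok]) > 0)
    speed_tests$head <- stats::t.test(hd[ok], hs[ok], paired = TRUE)

  movement <- NULL
  movs <- lapply(results, `[[`, "movement")
  if (sum(vapply(movs, function(m)
    !is.null(m) && is.finite(m$movement_mean), logical(1))) >= 2)
    movement <- compare_movement_vs_stimulus(Filter(Negate(is.null), movs))

  out <- list(npc1 = np, tests = tests, speed_tests = speed_tests,
              movement = movement, n_sessions = length(results))
  class(out) <- "group_result"
  out
}

#' Write a session report to disk
#'
#' Serializes a `session_result` as a versioned JSON report plus CSV tables
#' (per-trial scores and the gaze table) for external plotting.
#'
#' @param result A `session_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_session_report <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(
    schema_version = 1L,
    channel = result$channel,
    npc1 = as.list(result$npc1),
    tests = lapply(result$tests, perm_summary),
    speeds = result$speeds,
    head_eye_correlation = result$head_eye_correlation,
    movement = if (!is.null(result$movement))
      result$movement[c("n_epochs", "movement_mean", "stim_std_mean",
                        "stim_dev_mean")] else NULL,
    n_perm = result$n_perm, seed = result$seed,
    config_hash = result$config_hash)
  jsonlite::write_json(report, file.path(dir, "session_report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null")
  utils::write.csv(result$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  if (!is.null(result$gaze))
    utils::write.csv(as.data.frame(result$gaze), file.path(dir, "gaze.csv"),
                     row.names = FALSE)
  invisible(dir)
}
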
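#' Derive trial-group flags on a trial log
#'
#' Adds the three derived boolean columns used throughout the analysis:
#' `is_first10` (the first ten trials of the session), `is_1after` (a
#' standard trial immediately following a deviant) and a placeholder
#' `is_first_view` column (filled by the gaze stage when head tracking is
#' available).
#'
#' @param log Trial-log data.frame with `trial_index`, `onset_s`, `offset_s`,
#'   `condition`, `pos_col`, `pos_row`.
#' @return The log with flag columns, ordered by `trial_index`.
#' @export
derive_trial_flags <- function(log) {
  req <- c("trial_index", "onset_s", "offset_s", "condition", "pos_col", "pos_row")
  miss <- setdiff(req, names(log))
  if (length(miss))
    stop("trial log missing column(s): ", paste(miss, collapse = ", "))
  log <- log[order(log$trial_index), , drop = FALSE]
  if (any(diff(log$onset_s) <= 0))
    stop("trial log onsets must be strictly increasing")
  if (any(log$offset_s <= log$onset_s))
    stop("trial log offsets must exceed onsets")
  log$is_first10 <- log$trial_index < 10
  prev_dev <- c(FALSE, log$condition[-nrow(log)] == "deviant")
  log$is_1after <- prev_dev & log$condition == "standard"
  if (is.null(log$is_first_view)) log$is_first_view <- NA
  rownames(log) <- NULL
  log
}

write_matrix_bin <- function(voltage, fs, t0, path_bin, path_json) {
  con <- file(path_bin, "wb")
  on.exit(close(con))
  # channel-sequential blocks of float64 little-endian
  writeBin(as.numeric(t(voltage)), con, size = 8, endian = "little")
  jsonlite::write_json(
    list(n_channels = nrow(voltage), n_samples = ncol(voltage),
         fs_hz = fs, t0_s = t0, dtype = "float64",
         layout = "channel_blocks", byte_order = "little"),
    path_json, auto_unbox = TRUE, digits = NA)
}

read_matrix_bin <- function(path_bin, path_json) {
  meta <- jsonlite::read_json(path_json, simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path_bin, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = n, size = 8, endian = "little")
  if (length(v) != n)
    stop(sprintf("LFP binary '%s' truncated: expected %d samples, got %d",
                 path_bin, n, length(v)))
  rec <- list(voltage = matrix(v, nrow = meta$n_channels, byrow = TRUE),
              fs = meta$fs_hz, t0 = meta$t0_s)
  class(rec) <- "continuous_recording"
  rec
}

read_csv_strict <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = ",", quote = "\"")
  bad <- which(nf != nf[1])
  if (length(bad))
    stop(sprintf("malformed CSV '%s': line %d has %d fields (expected %d)",
                 path, bad[1], nf[bad[1]], nf[1]))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("CSV '%s' missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' Write a session to disk
#'
#' Serializes every artifact of an `oddball_session` into `dir`: the
#' continuous trace as float64 raw binary (`lfp.bin`) with a JSON sidecar
#' (`lfp.json`: channels, samples, `fs_hz`, `t0_s`), the trial log and
#' keypoint tables as CSV, the session configuration (including the
#' visual-streak angle `rho_deg` and the socket-outline annotation) as YAML,
#' and the planted ground truth as JSON.
#'
#' @param session An `oddball_session`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_matrix_bin(session$rec$voltage, session$rec$fs, session$rec$t0,
                   p("lfp.bin"), p("lfp.json"))
  utils::write.csv(session$log, p("trials.csv"), row.names = FALSE)
  utils::write.csv(session$head, p("head_keypoints.csv"), row.names = FALSE)
  if (!is.null(session$eye))
    utils::write.csv(session$eye, p("eye_keypoints.csv"), row.names = FALSE)
  cfg <- session$config
  cfg$grid$positions <- as.list(cfg$grid$positions)
  yaml::write_yaml(list(config = unclass(cfg),
                        socket = as.list(session$socket)),
                   p("session.yaml"))
  if (!is.null(session$truth)) {
    tr <- session$truth
    tr$head <- as.list(tr$head)
    if (!is.null(tr$eye)) tr$eye <- as.list(tr$eye)
    jsonlite::write_json(tr, p("ground_truth.json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(dir)
}

#' Load a session from disk
#'
#' Reads the artifacts written by [write_session()] (or equivalently
#' formatted real data) and aligns all streams on the common session clock.
#' The eye stream is optional; a missing eye table yields a head-only
#' session. Trial onsets outside the recording span raise an alignment
#' error; malformed CSVs raise a parse error naming the first bad line.
#'
#' @param dir Session directory.
#' @return An `oddball_session` (without `truth` unless a ground-truth file
#'   is present).
#' @export
load_session <- function(dir) {
  p <- function(f) file.path(dir, f)
  rec <- read_matrix_bin(p("lfp.bin"), p("lfp.json"))
  log <- read_csv_strict(p("trials.csv"),
                         c("trial_index", "onset_s", "offset_s", "condition",
                           "pos_col", "pos_row"))
  log <- derive_trial_flags(log)
  t_end <- rec$t0 + ncol(rec$voltage) / rec$fs
  if (any(log$onset_s < rec$t0) || any(log$offset_s > t_end))
    stop(sprintf("alignment error: trial onsets/offsets outside recording span [%g, %g] s",
                 rec$t0, t_end))
  kp_cols <- c("frame", "time_s", "point_name", "x_px", "y_px", "likelihood")
  head_kp <- read_csv_strict(p("head_keypoints.csv"), kp_cols)
  eye_kp <- if (file.exists(p("eye_keypoints.csv")))
    read_csv_strict(p("eye_keypoints.csv"), kp_cols) else NULL
  y <- yaml::read_yaml(p("session.yaml"))
  cfg <- y$config
  cfg$grid$positions <- as.data.frame(cfg$grid$positions)
  class(cfg) <- "session_config"
  truth <- NULL
  if (file.exists(p("ground_truth.json"))) {
    truth <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
    truth$head <- as.data.frame(truth$head)
    if (!is.null(truth$eye) && length(truth$eye))
      truth$eye <- as.data.frame(truth$eye)
  }
  session <- list(rec = rec, log = log, head = head_kp, eye = eye_kp,
                  socket = as.data.frame(y$socket), truth = truth,
                  config = cfg)
  class(session) <- "oddball_session"
  session
}

#' Drop keypoint rows below a likelihood threshold
#'
#' Markerless trackers attach a confidence to every keypoint; rows under the
#' threshold are removed before any geometric computation, so frames missing
#' a required point are excluded from per-trial averages.
#'
#' @param kp Keypoint table.
#' @param likelihood_min Threshold in \[0, 1\] (default 0.9).
#' @return Filtered keypoint table.
#' @export
filter_keypoints <- function(kp, likelihood_min = 0.9) {
  kp[kp$likelihood >= likelihood_min, , drop = FALSE]
}
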
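test_that("the 80-580 ms window at 20 kHz downsamples to exactly 200 block-averaged columns", {
  cfg <- session_config(n_trials = 8L, fs_lfp = 20000, include_eye = FALSE,
                        seed = 31)
  s <- generate_oddball_session(cfg)
  m <- extract_response_matrix(s$rec, s$log)
  expect_equal(ncol(m$data), 200L)
  expect_equal(m$fs_out, 400)
  # block averaging oracle on one trial: 50-sample non-overlapping means
  i <- 3
  s0 <- floor((s$log$onset_s[i] + 0.08) * 20000)
  raw <- s$rec$voltage[1, (s0 + 1):(s0 + 10000)]
  expect_equal(m$data[i, ], colMeans(matrix(raw, nrow = 50)))
  # downsampling preserves the window mean exactly
  expect_equal(mean(m$data[i, ]), mean(raw))
  # offset alignment reuses the same arithmetic on a different anchor
  mo <- extract_response_matrix(s$rec, s$log, align = "offset")
  expect_equal(ncol(mo$data), 200L)
  s0o <- floor((s$log$offset_s[i] + 0.08) * 20000)
  expect_equal(mo$data[i, ],
               colMeans(matrix(s$rec$voltage[1, (s0o + 1):(s0o + 10000)],
                               nrow = 50)))
})

test_that("rates not divisible by 400 and windows past the recording are rejected", {
  rec <- mini_rec(rnorm(5000), fs = 1000)
  log <- mini_log(1, "standard")
  expect_error(extract_response_matrix(rec, log), "divisible by 400")
  rec2 <- mini_rec(rnorm(2000), fs = 2000)  # 1 s of data
  expect_error(extract_response_matrix(rec2, mini_log(0.9, "standard")),
               "past the recording")
})

test_that("trials with an artifact sample in the window are masked out", {
  cfg <- fast_config(n_trials = 30L, seed = 32)
  s <- generate_oddball_session(cfg)
  bad <- 7L  # 0-based trial 7: plant a 950 uV sample mid-window
  idx <- floor((s$log$onset_s[bad + 1] + 0.3) * s$rec$fs) + 1
  s$rec$voltage[1, idx] <- 950
  m <- extract_response_matrix(s$rec, s$log)
  expect_true(m$artifact_mask[bad + 1])
  expect_false(bad %in% m$trial_index)
  expect_equal(nrow(m$data), 29L)
  expect_true(all(abs(m$data) <= 900))
})

two_cluster_matrix <- function(a = 5, n = 20, d = 200, eps = 0.05, seed = 1) {
  set.seed(seed)
  u <- rnorm(d); u <- u / sqrt(sum(u^2))
  rows <- rbind(matrix(rep(-a * u, n), n, byrow = TRUE),
                matrix(rep(+a * u, n), n, byrow = TRUE)) +
    matrix(rnorm(2 * n * d, sd = eps), 2 * n)
  log <- mini_log(seq(5, by = 7, length.out = 2 * n),
                  rep(c("standard", "deviant"), each = n))
  m <- structure(list(data = rows, trial_index = log$trial_index,
                      artifact_mask = rep(FALSE, 2 * n), channel = 1L,
                      fs_out = 400, window = c(0.08, 0.58), align = "onset"),
                 class = "response_matrix")
  list(m = m, log = log, u = u)
}

test_that("the balanced repeated axis recovers a planted separation direction", {
  tc <- two_cluster_matrix()
  fit <- fit_balanced_pc1(tc$m, tc$log, seed = 2)
  expect_gt(abs(sum(fit$axis * tc$u)), 0.99)
  expect_equal(sqrt(sum(fit$axis^2)), 1, tolerance = 1e-12)
  expect_equal(fit$n_repeats, 100L)
  # independent oracle: leading eigenvector of the balanced covariance
  ev <- eigen(stats::cov(tc$m$data))$vectors[, 1]
  expect_gt(abs(sum(fit$axis * ev)), 0.99)
  # orientation: deviant scores above standard scores
  sc <- project_scores(tc$m, fit, tc$log)
  expect_gte(mean(sc$score[sc$condition == "deviant"]),
             mean(sc$score[sc$condition == "standard"]))
})

test_that("a single repeat equals one balanced PCA (oracle equivalence)", {
  tc <- two_cluster_matrix(eps = 0.5, seed = 3)
  fit <- fit_balanced_pc1(tc$m, tc$log, n_repeats = 1L, seed = 7)
  # mirror the internal draw: first RNG use after the seed is the standard draw
  set.seed(7)
  std_rows <- which(tc$log$condition == "standard")
  dev_rows <- which(tc$log$condition == "deviant")
  sub <- tc$m$data[c(dev_rows, sample(std_rows, 20)), ]
  ctr <- colMeans(sub)
  v <- svd(sweep(sub, 2, ctr), nu = 0, nv = 1)$v[, 1]
  expect_equal(abs(sum(fit$axis * v)), 1, tolerance = 1e-9)
  expect_equal(fit$center, ctr)
})

test_that("identical rows and insufficient group sizes are rejected", {
  n <- 44
  rows <- matrix(1, n, 200)
  log <- mini_log(seq(5, by = 7, length.out = n),
                  rep(c("standard", "deviant"), each = n / 2))
  m <- structure(list(data = rows, trial_index = log$trial_index,
                      artifact_mask = rep(FALSE, n), channel = 1L,
                      fs_out = 400, window = c(0.08, 0.58), align = "onset"),
                 class = "response_matrix")
  expect_error(fit_balanced_pc1(m, log, seed = 1), "degenerate")
  tc <- two_cluster_matrix(n = 10)
  expect_error(fit_balanced_pc1(tc$m, tc$log, seed = 1), "deviant")
})

test_that("projection matches the brute-force dot product and is shift invariant", {
  tc <- two_cluster_matrix(eps = 1, seed = 5)
  fit <- fit_balanced_pc1(tc$m, tc$log, seed = 9)
  sc <- project_scores(tc$m, fit, tc$log)
  brute <- vapply(seq_len(nrow(tc$m$data)), function(i)
    fit$orientation_sign *
      sum((tc$m$data[i, ] - fit$center) * fit$axis), numeric(1))
  expect_equal(sc$score, brute)
  # a row equal to the centre scores 0
  m1 <- tc$m; m1$data[1, ] <- fit$center
  expect_equal(project_scores(m1, fit, tc$log)$score[1], 0)
  # adding a constant to every sample of every trial leaves scores unchanged
  mshift <- tc$m; mshift$data <- mshift$data + 123.4
  fit2 <- fit_balanced_pc1(mshift, tc$log, seed = 9)
  expect_equal(project_scores(mshift, fit2, tc$log)$score, sc$score,
               tolerance = 1e-8)
  # dimension mismatch guard
  mbad <- tc$m; mbad$data <- mbad$data[, 1:100]
  expect_error(project_scores(mbad, fit, tc$log), "mismatch")
})

test_that("nPC1 follows (m_X - m_Std) / s_Std with Standard pinned at zero", {
  # craft scores through a trivial axis so group stats are fully controlled
  n <- 40
  std_scores <- rep(c(1, 3), 10)            # mean 2, sd ~1.026
  dev_scores <- rep(5, 10)
  rows <- matrix(0, n, 200)
  rows[, 1] <- c(rep(0, 10), std_scores, dev_scores)  # first 10 = first10 trials
  log <- mini_log(seq(5, by = 7, length.out = n),
                  c(rep("standard", 30), rep("deviant", 10)))
  m <- structure(list(data = rows, trial_index = log$trial_index,
                      artifact_mask = rep(FALSE, n), channel = 1L,
                      fs_out = 400, window = c(0.08, 0.58), align = "onset"),
                 class = "response_matrix")
  model <- structure(list(center = rep(0, 200),
                          axis = c(1, rep(0, 199)), orientation_sign = 1,
                          n_repeats = 1L, n_per_group = 10L, seed = 1L),
                     class = "pc_model")
  sc <- project_scores(m, model, log)
  np <- npc1(sc)
  s_std <- sd(std_scores)
  expect_equal(np[["standard"]], 0)
  expect_equal(np[["deviant"]], (5 - 2) / s_std)
  expect_equal(np[["first10"]], (0 - 2) / s_std)
  # a group exactly 2 SDs above the standard mean lands at nPC1 = 2
  expect_equal((2 + 2 * s_std - 2) / s_std, 2)
  # zero standard spread cannot be normalized
  rows2 <- rows; rows2[11:30, 1] <- 2
  m2 <- m; m2$data <- rows2
  expect_error(project_scores(m2, model, log), "sPC1_Standard")
})

test_that("control projection flips with a negative raw novelty direction and flags bias-explained sessions", {
  # genuine deviance, unbiased control: not explained by spatial bias
  cfg <- fast_config(seed = 41)
  odd <- generate_oddball_session(cfg)
  mo <- extract_response_matrix(odd$rec, odd$log)
  fit <- fit_balanced_pc1(mo, odd$log, seed = 6)
  sc <- project_scores(mo, fit, odd$log)
  ctl <- generate_control_session(fast_config(seed = 42))
  mc <- extract_response_matrix(ctl$rec, ctl$log)
  pc <- project_control_session(mc, fit, ctl$log, sc, cfg$grid,
                                n_perm = 999, seed = 8)
  expect_false(pc$bias_explained)
  expect_equal(nrow(pc$position_means), 5)
  expect_equal(pc$flipped, fit$orientation_sign < 0)

  # apparent "novelty" that is really a doubled response at the deviant
  # position: the matching biased control explains it away
  cfgp <- fast_config(gain_deviant = 2, gain_standard_initial = 1,
                      adaptation_tau_trials = Inf, seed = 43)
  odd2 <- generate_oddball_session(cfgp)
  mo2 <- extract_response_matrix(odd2$rec, odd2$log)
  fit2 <- fit_balanced_pc1(mo2, odd2$log, seed = 6)
  sc2 <- project_scores(mo2, fit2, odd2$log)
  bias <- rep(1, 5); bias[cfgp$grid$deviant] <- 2
  # noiseless control: the planted position bias is estimated exactly
  ctl2 <- generate_control_session(
    fast_config(gain_standard_initial = 1, adaptation_tau_trials = Inf,
                noise_sd_uv = 0, seed = 44), position_bias = bias)
  mc2 <- extract_response_matrix(ctl2$rec, ctl2$log)
  pc2 <- project_control_session(mc2, fit2, ctl2$log, sc2, cfgp$grid,
                                 n_perm = 999, seed = 8)
  expect_true(pc2$bias_explained)
  expect_lt(pc2$npc1_adjusted, 2)

  # the flip rule negates all control scores when the raw direction is negative
  fit_neg <- fit2; fit_neg$axis <- -fit_neg$axis
  fit_neg$orientation_sign <- -fit_neg$orientation_sign
  pc3 <- project_control_session(mc2, fit_neg, ctl2$log, sc2, cfgp$grid,
                                 n_perm = 99, seed = 8)
  expect_equal(pc3$scores$score, pc2$scores$score)
  expect_true(xor(pc2$flipped, pc3$flipped))
})

test_that("the analysis channel is the one with maximal window-mean variance across trials", {
  cfg <- fast_config(n_trials = 30L, n_channels = 3L,
                     channel_gains = c(0.2, 1.5, 0.6), seed = 45)
  s <- generate_oddball_session(cfg)
  expect_equal(select_channel(s$rec, s$log), 2L)
})

test_that("noiseless PC1 scores reproduce the planted gains up to an affine map", {
  cfg <- fast_config(noise_sd_uv = 0, seed = 46)
  s <- generate_oddball_session(cfg)
  m <- extract_response_matrix(s$rec, s$log)
  fit <- fit_balanced_pc1(m, s$log, seed = 2)
  sc <- project_scores(m, fit, s$log)
  g <- s$truth$gain[match(sc$trial_index, s$log$trial_index)]
  expect_equal(unname(pearson_correlation(sc$score, g)$r), 1,
               tolerance = 1e-9)
})
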
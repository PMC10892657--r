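# Synthetic cohort generator: population sampling, keystroke waveform,
# coupling law, forward kinematics, and the trajectory CSV dialect.

test_that("sample_subjects draws from the configured population", {
  # degenerate SD pins every subject at the population mean
  p0 <- sample_subjects(5, middle_sd = 0, ring_sd = 0, seed = 1)
  expect_equal(p0$middle_length_mm, rep(84.4, 5))
  expect_equal(p0$ring_length_mm, rep(79.1, 5))

  # law of large numbers against the configured means
  p <- sample_subjects(10000, seed = 42)
  expect_lt(abs(mean(p$middle_length_mm) - 84.4), 0.2)
  expect_lt(abs(mean(p$ring_length_mm) - 79.1), 0.2)
  expect_true(all(p$middle_length_mm > 40 & p$middle_length_mm < 130))
  expect_true(all(p$training_years >= 5 & p$training_years <= 15))

  # deterministic for a fixed seed
  expect_identical(sample_subjects(4, seed = 7), sample_subjects(4, seed = 7))
  expect_error(sample_subjects(0), class = "ringcast_argument_error")
})

test_that("keystroke waveform has the stated rest, peak and integral", {
  expect_equal(middle_mcp_profile(0, 0.75, 40, 10), 10)
  expect_equal(middle_mcp_profile(0.375, 0.75, 40, 10), 50)
  # closed-form integral over one cycle: rest*T + amplitude*T/2
  integ <- stats::integrate(function(t) middle_mcp_profile(t, 0.75, 40, 10),
                            0, 0.75 - 1e-12)$value
  expect_equal(integ, 10 * 0.75 + 40 * 0.75 / 2, tolerance = 1e-6)
  expect_error(middle_mcp_profile(0.75, 0.75, 40, 10),
               class = "ringcast_argument_error")
  expect_error(middle_mcp_profile(-0.1, 0.75, 40, 10),
               class = "ringcast_argument_error")
})

test_that("coupling law reproduces identity, scaling, and an explicit lag", {
  prof <- fixed_profile()
  t <- (0:299) / 100
  theta <- middle_mcp_profile(t %% 0.75, 0.75, 40, 10)

  ident <- coupling_law(gain_base = 1, gain_length_coeff = 0,
                        gain_training_coeff = 0, lag_s = 0, offset_deg = 0)
  expect_equal(true_ring_angle(theta, t, prof, ident), theta)

  scaled <- coupling_law(gain_base = 0.8, gain_length_coeff = 0,
                         gain_training_coeff = 0, lag_s = 0, offset_deg = 0)
  expect_equal(true_ring_angle(rep(50, 300), t, prof, scaled), rep(40, 300))

  # lag of exactly 2 sample periods: index-shift oracle after the warm-up
  lagged <- coupling_law(gain_base = 1, gain_length_coeff = 0,
                         gain_training_coeff = 0, lag_s = 0.02,
                         offset_deg = 0)
  beta <- true_ring_angle(theta, t, prof, lagged)
  expect_equal(beta[3:300], theta[1:298])
  expect_equal(beta[1:2], rep(theta[1], 2))

  expect_error(true_ring_angle(theta, t[-1], prof, ident),
               class = "ringcast_argument_error")
})

test_that("generated sessions respect the protocol counts and rigidity", {
  prof <- fixed_profile()
  cfg <- noisy_config(sets = 3, keystrokes = 4)
  sets <- generate_session(prof, cfg)
  expect_length(sets, 3)
  fpc <- round(0.75 * 100)
  expect_length(sets[[1]]$time_s, 4 * fpc)

  # total cycles = sets x keystrokes after segmentation
  n_cycles <- sum(vapply(sets, function(s) {
    nrow(segment_cycles(extract_angles(s), 0.75)$cycle_bounds)
  }, integer(1)))
  expect_identical(n_cycles, 12L)

  # determinism: identical (profile, config, seed) -> identical data
  expect_identical(sets, generate_session(prof, cfg))

  # noiseless mode: planarity and phalanx rigidity
  s0 <- generate_session(prof, noiseless_config())[[1]]
  expect_true(all(s0$positions[, , , 1] == 0))
  for (fi in 1:2) {
    len <- phalanx_lengths(if (fi == 1) prof$middle_length_mm else prof$ring_length_mm)
    for (j in 1:3) {
      d <- sqrt(rowSums((s0$positions[, fi, j + 1, ] -
                           s0$positions[, fi, j, ])^2))
      expect_lt(max(abs(d - len[j])), 1e-6)
    }
  }
})

test_that("noiseless generation round-trips through angle extraction", {
  prof <- fixed_profile()
  cfg <- noiseless_config(keystrokes = 5)
  ser <- extract_angles(generate_session(prof, cfg)[[1]])
  fpc <- round(cfg$cycle_period_s * cfg$sample_rate_hz)
  t_in <- ((seq_along(ser$time_s) - 1) %% fpc) / cfg$sample_rate_hz
  truth <- middle_mcp_profile(t_in, cfg$cycle_period_s, cfg$amplitude_deg,
                              cfg$rest_angle_deg)
  expect_lt(max(abs(ser$theta1_deg - truth)), 1e-9)
  beta_truth <- true_ring_angle(truth, ser$time_s, prof, cfg$coupling)
  expect_lt(max(abs(ser$beta1_deg - beta_truth)), 1e-9)
})

test_that("trajectory CSV round-trips and rejects malformed input", {
  prof <- fixed_profile()
  traj <- generate_session(prof, noisy_config(sets = 1, keystrokes = 2))[[1]]
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  back <- read_trajectory(path)
  expect_equal(back$subject_id, traj$subject_id)
  expect_equal(back$time_s, traj$time_s, tolerance = 1e-6)
  expect_lt(max(abs(back$positions - traj$positions)), 1e-6)

  # empty trajectory refuses to write
  empty <- traj
  empty$time_s <- numeric(0)
  expect_error(write_trajectory(empty, path),
               class = "ringcast_argument_error")

  # non-monotone time column -> parse error naming a line
  df <- utils::read.csv(path)
  bad_row <- 8 * 5 + 1  # first row of frame 6
  df$time_s[bad_row:(bad_row + 7)] <- 0
  bad_path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(read_trajectory(bad_path), "non-monotone",
               class = "ringcast_parse_error")

  # missing column -> schema error naming the column
  df2 <- utils::read.csv(path)
  df2$z_mm <- NULL
  utils::write.csv(df2, bad_path, row.names = FALSE, quote = FALSE)
  expect_error(read_trajectory(bad_path), "z_mm",
               class = "ringcast_schema_error")
})
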
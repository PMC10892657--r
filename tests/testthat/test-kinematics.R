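# Joint-angle extraction, finite differences, smoothing, cycle segmentation.

test_that("mcp_angle matches hand-computed geometry and stays in [0, 180]", {
  expect_equal(mcp_angle(c(0, 0, 0), c(0, 0, 40)), 0)
  expect_equal(mcp_angle(c(0, 0, 0), c(0, 40, 0)), 90)
  # acos((0*0 + 0*20 + 1*(-20*sqrt(3))) / 40) = 150 degrees
  expect_equal(mcp_angle(c(0, 0, 0), c(0, 20, -20 * sqrt(3))), 150)
  expect_error(mcp_angle(c(1, 2, 3), c(1, 2, 3)),
               class = "ringcast_degenerate_error")

  # clamping guard: numerically (anti)parallel vectors never yield NaN
  for (s in c(1, -1)) {
    v <- s * c(0, 0, 1 + 1e-15)
    expect_false(is.nan(mcp_angle(c(0, 0, 0), v)))
  }
})

test_that("theta1 is invariant to rotation about the vertical axis", {
  set.seed(3)
  for (i in 1:20) {
    p0 <- rnorm(3)
    p1 <- p0 + rnorm(3)
    phi <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(phi), -sin(phi), 0), c(sin(phi), cos(phi), 0), c(0, 0, 1))
    expect_equal(mcp_angle(as.vector(R %*% p0), as.vector(R %*% p1)),
                 mcp_angle(p0, p1))
  }
})

test_that("differentiate is second-order accurate and exactly linear", {
  t <- (0:199) / 100
  expect_equal(differentiate(rep(30, 200), t), rep(0, 200))
  expect_equal(differentiate(10 * t, t), rep(10, 200))

  # analytic-derivative oracle for a keystroke-period sinusoid at 100 Hz
  theta <- 40 * sin(2 * pi * t / 0.75)
  truth <- 40 * (2 * pi / 0.75) * cos(2 * pi * t / 0.75)
  err <- abs(differentiate(theta, t) - truth)
  expect_lt(max(err[2:199]), 0.5)            # central-difference bound
  h <- 0.01
  end_bound <- 40 * (2 * pi / 0.75)^3 * h^2 / 3  # one-sided stencil bound
  expect_lt(max(err[c(1, 200)]), 1.1 * end_bound)

  # linearity holds exactly
  f <- rnorm(50)
  g <- rnorm(50)
  tt <- (0:49) / 100
  expect_equal(differentiate(2 * f + 3 * g, tt),
               2 * differentiate(f, tt) + 3 * differentiate(g, tt))

  expect_error(differentiate(1:2, c(0, 0.01)),
               class = "ringcast_argument_error")
  expect_error(differentiate(1:4, c(0, 0.01, 0.03, 0.04)),
               class = "ringcast_argument_error")
})

test_that("extract_angles reports straight fingers as zero IP angles", {
  n <- 10
  pos <- array(0, dim = c(n, 2, 4, 3))
  for (j in 1:4) pos[, , j, 3] <- -(j - 1) * 30  # joints straight down -Z0
  traj <- structure(list(subject_id = "s", set_index = 1L,
                         time_s = (0:(n - 1)) / 100, positions = pos),
                    class = "hand_trajectory")
  ser <- extract_angles(traj)
  expect_equal(ser$theta2_deg, rep(0, n))
  expect_equal(ser$theta3_deg, rep(0, n))
  expect_equal(ser$theta1_deg, rep(180, n))
})

test_that("moving-average smoothing reduces angle noise as expected", {
  prof <- fixed_profile()
  cfg <- generator_config(n_subjects = 1, sets_per_subject = 1,
                          keystrokes_per_set = 20, angle_noise_sd_deg = 2,
                          position_noise_sd_mm = 0, seed = 9)
  traj <- generate_session(prof, cfg)[[1]]
  ser <- extract_angles(traj, smoothing_window = 5)
  fpc <- round(cfg$cycle_period_s * cfg$sample_rate_hz)
  t_in <- ((seq_along(ser$time_s) - 1) %% fpc) / cfg$sample_rate_hz
  truth <- middle_mcp_profile(t_in, cfg$cycle_period_s, cfg$amplitude_deg,
                              cfg$rest_angle_deg)
  # window-5 averaging cuts the 2-degree noise SD by about sqrt(5)
  expect_lt(sd(ser$theta1_deg - truth), 2)
  raw <- extract_angles(traj, smoothing_window = 1)
  expect_gt(sd(raw$theta1_deg - truth), sd(ser$theta1_deg - truth))
})

test_that("cycle segmentation follows floor arithmetic on the duration", {
  prof <- fixed_profile()
  ser <- extract_angles(generate_session(prof, noiseless_config(keystrokes = 25))[[1]])
  ser <- segment_cycles(ser, 0.75)
  expect_identical(nrow(ser$cycle_bounds), 25L)
  expect_true(all(ser$cycle_bounds[, "end"] - ser$cycle_bounds[, "start"] == 75L))
  expect_true(all(diff(ser$cycle_bounds[, "start"]) == 75L))

  # duration of exactly one period -> one cycle
  one <- extract_angles(generate_session(prof, noiseless_config(keystrokes = 1))[[1]])
  expect_identical(nrow(segment_cycles(one, 0.75)$cycle_bounds), 1L)

  # non-integer number of periods: remainder dropped by floor arithmetic
  frac <- extract_angles(
    generate_session(prof, noiseless_config(keystrokes = 2))[[1]])
  # 150 frames / 13-frame windows = 11.54 periods -> 11 cycles
  expect_identical(nrow(segment_cycles(frac, 0.13)$cycle_bounds),
                   as.integer(floor(length(frac$time_s) / 13)))
  expect_error(segment_cycles(frac, 0.01), class = "ringcast_argument_error")
})
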
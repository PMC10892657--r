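# Synthetic keystroke-session generator: metronome-paced MCP flexion pulses,
# an injected middle->ring coupling, planar forward kinematics, sensor noise.

#' Configure the synthetic keystroke generator
#'
#' Defaults reproduce the measurement protocol of the emulated study: a
#' 12-subject cohort, 30 sets of 25 metronome-paced keystrokes per subject,
#' one action cycle every 0.75 s, sampled at 100 Hz (Leap-Motion-class
#' devices run 50-120 Hz), with 2 degrees of angle-domain sensor noise and
#' 0.5 mm of position noise.
#'
#' @param n_subjects,sets_per_subject,keystrokes_per_set Cohort counts (>= 1).
#' @param cycle_period_s Keystroke cycle period (s).
#' @param sample_rate_hz Sampling rate (Hz); at least 20 frames per cycle are
#'   required.
#' @param rest_angle_deg,amplitude_deg Rest angle and flexion amplitude
#'   (degrees) of the middle-finger MCP pulse.
#' @param ip_ratio_pip,ip_ratio_dip PIP/DIP excursion as a fraction of the MCP
#'   excursion above rest (shapes the generated finger curl; the model itself
#'   only uses MCP angles).
#' @param angle_noise_sd_deg SD (degrees) of Gaussian noise added to every
#'   generating joint angle before forward kinematics.
#' @param position_noise_sd_mm SD (mm) of Gaussian noise added to each joint
#'   coordinate after forward kinematics.
#' @param coupling A [coupling_law()] giving the ground-truth beta1 = f(theta1).
#' @param seed Integer seed; generation is bit-reproducible given
#'   (profile, config, seed).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_subjects = 12L,
                             sets_per_subject = 30L,
                             keystrokes_per_set = 25L,
                             cycle_period_s = 0.75,
                             sample_rate_hz = 100,
                             rest_angle_deg = 10,
                             amplitude_deg = 40,
                             ip_ratio_pip = 0.5,
                             ip_ratio_dip = 0.3,
                             angle_noise_sd_deg = 2,
                             position_noise_sd_mm = 0.5,
                             coupling = coupling_law(),
                             seed = 1L) {
  counts <- c(n_subjects, sets_per_subject, keystrokes_per_set)
  if (any(counts < 1) || any(counts != round(counts))) {
    arg_error("all cohort counts must be integers >= 1")
  }
  if (cycle_period_s <= 0 || sample_rate_hz <= 0) {
    arg_error("cycle_period_s and sample_rate_hz must be positive")
  }
  if (sample_rate_hz * cycle_period_s < 20) {
    arg_error("need at least 20 frames per keystroke cycle")
  }
  if (angle_noise_sd_deg < 0 || position_noise_sd_mm < 0) {
    arg_error("noise SDs must be >= 0")
  }
  if (amplitude_deg <= 0 || amplitude_deg >= 90) {
    arg_error("amplitude_deg must lie in (0, 90)")
  }
  stopifnot(inherits(coupling, "coupling_law"))
  if (coupling$lag_s > cycle_period_s / 4) {
    arg_error("coupling lag_s must lie in [0, cycle_period_s/4]")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         sets_per_subject = as.integer(sets_per_subject),
         keystrokes_per_set = as.integer(keystrokes_per_set),
         cycle_period_s = cycle_period_s,
         sample_rate_hz = sample_rate_hz,
         rest_angle_deg = rest_angle_deg,
         amplitude_deg = amplitude_deg,
         ip_ratio_pip = ip_ratio_pip,
         ip_ratio_dip = ip_ratio_dip,
         angle_noise_sd_deg = angle_noise_sd_deg,
         position_noise_sd_mm = position_noise_sd_mm,
         coupling = coupling,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

#' Middle-finger MCP angle profile within one keystroke cycle
#'
#' A C2-smooth flexion-extension pulse: the angle starts and ends each cycle
#' at the rest angle and peaks at `rest + amplitude` mid-cycle,
#' `theta1(t) = rest + amplitude * sin^2(pi * t / T)`.
#'
#' @param t_in_cycle Time(s) within the cycle, in `[0, cycle_period_s)`.
#' @param cycle_period_s Cycle period T (s).
#' @param amplitude_deg Peak flexion above rest (degrees), in (0, 90).
#' @param rest_angle_deg Rest angle (degrees).
#' @return theta1 in degrees, same length as `t_in_cycle`.
#' @export
#' @examples
#' middle_mcp_profile(0.375, 0.75, 40, 10)  # mid-cycle peak: 50 degrees
middle_mcp_profile <- function(t_in_cycle, cycle_period_s = 0.75,
                               amplitude_deg = 40, rest_angle_deg = 10) {
  if (any(t_in_cycle < 0 | t_in_cycle >= cycle_period_s)) {
    arg_error("t_in_cycle must lie in [0, cycle_period_s)")
  }
  if (amplitude_deg <= 0 || amplitude_deg >= 90) {
    arg_error("amplitude_deg must lie in (0, 90)")
  }
  rest_angle_deg + amplitude_deg * sin(pi * t_in_cycle / cycle_period_s)^2
}

#' Ground-truth ring-finger MCP angle from a middle-finger angle series
#'
#' Applies the injected coupling law: `beta1(t) = offset + gain(profile) *
#' theta1(t - lag)`, where the gain depends on the subject's finger-length
#' difference and training years. theta1 before the start of the recording is
#' extended by its initial (rest) value. With the `"tanh"` saturation variant
#' the coupled term is passed through `S * tanh(. / S)`.
#'
#' @param theta_deg Middle-finger MCP angle series (degrees).
#' @param time_s Time stamps (s), same length as `theta_deg`.
#' @param profile One-row subject profile (see [sample_subjects()]).
#' @param law A [coupling_law()].
#' @return beta1 in degrees, same length as `theta_deg`.
#' @export
true_ring_angle <- function(theta_deg, time_s, profile, law = coupling_law()) {
  if (length(theta_deg) != length(time_s)) {
    arg_error("theta_deg and time_s must have equal length")
  }
  if (nrow(profile) != 1L) arg_error("profile must be a single row")
  gain <- coupling_gain(law, profile)
  if (gain <= 0 || gain >= 2) {
    arg_error(sprintf("coupling gain %.3f outside (0, 2) for subject %s",
                      gain, profile$subject_id))
  }
  lagged <- if (law$lag_s == 0) theta_deg else {
    stats::approx(time_s, theta_deg, xout = time_s - law$lag_s, rule = 2)$y
  }
  coupled <- gain * lagged
  if (law$saturation == "tanh") {
    coupled <- law$sat_scale_deg * tanh(coupled / law$sat_scale_deg)
  }
  law$offset_deg + coupled
}

# Phalanx lengths (proximal, middle, distal) from total finger length, using
# a standard anthropometric split; only their sum matters to the MCP model.
phalanx_lengths <- function(total_length_mm) {
  total_length_mm * c(0.46, 0.31, 0.23)
}

# Planar forward kinematics in the Y0-Z0 plane. Absolute segment angles from
# the vertical Z0 axis are cumulative: a1 = mcp, a2 = mcp + pip, a3 = a2 + dip.
# Returns an n x 4 x 3 array of joint centres P0..P3 (x = 0 everywhere).
fk_chain <- function(mcp_deg, pip_deg, dip_deg, lengths_mm, origin = c(0, 0, 0)) {
  n <- length(mcp_deg)
  a1 <- mcp_deg * pi / 180
  a2 <- a1 + pip_deg * pi / 180
  a3 <- a2 + dip_deg * pi / 180
  pos <- array(0, dim = c(n, 4L, 3L))
  pos[, 1L, 1L] <- origin[1]
  pos[, 1L, 2L] <- origin[2]
  pos[, 1L, 3L] <- origin[3]
  pos[, 2L, 2L] <- pos[, 1L, 2L] + lengths_mm[1] * sin(a1)
  pos[, 2L, 3L] <- pos[, 1L, 3L] + lengths_mm[1] * cos(a1)
  pos[, 3L, 2L] <- pos[, 2L, 2L] + lengths_mm[2] * sin(a2)
  pos[, 3L, 3L] <- pos[, 2L, 3L] + lengths_mm[2] * cos(a2)
  pos[, 4L, 2L] <- pos[, 3L, 2L] + lengths_mm[3] * sin(a3)
  pos[, 4L, 3L] <- pos[, 3L, 3L] + lengths_mm[3] * cos(a3)
  pos
}

new_hand_trajectory <- function(subject_id, set_index, time_s, positions) {
  if (!all(is.finite(positions))) arg_error("trajectory contains non-finite positions")
  structure(
    list(subject_id = subject_id,
         set_index = as.integer(set_index),
         time_s = time_s,
         positions = positions),
    class = "hand_trajectory"
  )
}

#' @export
print.hand_trajectory <- function(x, ...) {
  cat(sprintf("<hand_trajectory> subject %s, set %d: %d frames (%.2f s)\n",
              x$subject_id, x$set_index, length(x$time_s),
              diff(range(x$time_s))))
  invisible(x)
}

#' Generate one subject's keystroke sets
#'
#' Builds `sets_per_subject` metronome-locked recordings. Per set: the
#' middle-finger MCP angle follows the sin^2 keystroke pulse; the ring-finger
#' MCP angle is derived through the coupling law; PIP/DIP angles follow the
#' MCP excursion with fixed ratios; Gaussian angle noise (if configured) is
#' added to every generating angle; planar forward kinematics in the Y0-Z0
#' plane places the joint centres P0 (MCP), P1 (PIP), P2 (DIP) and P3 (TIP)
#' of both fingers; optional position noise is added last.
#'
#' @param profile One-row subject profile.
#' @param config A [generator_config()]. `config$n_subjects` is ignored here;
#'   one call generates one subject.
#' @return A list of `hand_trajectory` objects, one per set, each with a
#'   positions array of dimension frames x finger(2: middle, ring) x
#'   joint(4: P0..P3) x coordinate(3: x, y, z mm).
#' @export
generate_session <- function(profile, config = generator_config()) {
  validate_profiles(profile)
  if (nrow(profile) != 1L) arg_error("profile must be a single row")
  fpc <- round(config$cycle_period_s * config$sample_rate_hz)
  n <- config$keystrokes_per_set * fpc
  idx <- seq_len(n) - 1L
  time_s <- idx / config$sample_rate_hz
  t_in <- (idx %% fpc) / config$sample_rate_hz
  rest <- config$rest_angle_deg
  lm_mid <- phalanx_lengths(profile$middle_length_mm)
  lm_ring <- phalanx_lengths(profile$ring_length_mm)

  theta1_clean <- middle_mcp_profile(t_in, config$cycle_period_s,
                                     config$amplitude_deg, rest)
  beta1_clean <- true_ring_angle(theta1_clean, time_s, profile, config$coupling)
  beta_rest <- true_ring_angle(rep(rest, 2L), time_s[1:2], profile,
                               config$coupling)[1]

  with_seed(config$seed, {
    lapply(seq_len(config$sets_per_subject), function(s) {
      noise <- function(x) {
        if (config$angle_noise_sd_deg > 0) {
          x + stats::rnorm(n, 0, config$angle_noise_sd_deg)
        } else x
      }
      th1 <- noise(theta1_clean)
      th2 <- noise(config$ip_ratio_pip * (theta1_clean - rest))
      th3 <- noise(config$ip_ratio_dip * (theta1_clean - rest))
      be1 <- noise(beta1_clean)
      be2 <- noise(config$ip_ratio_pip * (beta1_clean - beta_rest))
      be3 <- noise(config$ip_ratio_dip * (beta1_clean - beta_rest))

      pos <- array(0, dim = c(n, 2L, 4L, 3L),
                   dimnames = list(NULL, c("middle", "ring"),
                                   c("P0", "P1", "P2", "P3"),
                                   c("x", "y", "z")))
      pos[, 1L, , ] <- fk_chain(th1, th2, th3, lm_mid)
      pos[, 2L, , ] <- fk_chain(be1, be2, be3, lm_ring)
      if (config$position_noise_sd_mm > 0) {
        pos <- pos + stats::rnorm(length(pos), 0, config$position_noise_sd_mm)
      }
      new_hand_trajectory(profile$subject_id, s, time_s, pos)
    })
  })
}
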
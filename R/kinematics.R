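# MCP joint kinematics: angles from joint-centre positions, finite-difference
# velocities/accelerations, metronome-locked cycle segmentation.

#' MCP flexion angle from two joint centres
#'
#' The MCP rotation angle is the angle between the vertical up axis Z0 and the
#' proximal-phalanx vector P0->P1:
#' `theta1 = acos(u_Z0 . (P1 - P0) / |P1 - P0|)`, reported in degrees in
#' `[0, 180]`. The dot product is clamped to `[-1, 1]` before `acos` so the
#' result is never NaN for valid segments.
#'
#' @param p0,p1 Length-3 numeric vectors, joint centres in mm.
#' @param up_axis Reference axis (default Z0 = `c(0, 0, 1)`); normalized
#'   internally.
#' @return Angle in degrees.
#' @export
#' @examples
#' mcp_angle(c(0, 0, 0), c(0, 40, 0))  # 90
mcp_angle <- function(p0, p1, up_axis = c(0, 0, 1)) {
  stopifnot(length(p0) == 3L, length(p1) == 3L, length(up_axis) == 3L)
  v <- p1 - p0
  nv <- sqrt(sum(v^2))
  if (nv <= 1e-6) abort("coincident joint centres: segment length <= 1e-6 mm",
                        "ringcast_degenerate_error")
  u <- up_axis / sqrt(sum(up_axis^2))
  acos(clamp(sum(u * v) / nv, -1, 1)) * 180 / pi
}

# Vectorized angle between an n x 3 matrix of segment vectors and the up axis.
segment_angle_up <- function(v, up_axis = c(0, 0, 1), what = "segment") {
  nv <- sqrt(rowSums(v^2))
  bad <- which(nv <= 1e-6)
  if (length(bad)) {
    abort(sprintf("degenerate %s at frame(s) %s", what,
                  paste(utils::head(bad, 10L), collapse = ", ")),
          "ringcast_degenerate_error")
  }
  u <- up_axis / sqrt(sum(up_axis^2))
  acos(clamp((v %*% u)[, 1] / nv, -1, 1)) * 180 / pi
}

# Vectorized angle between consecutive segment vectors (rows of a and b).
segment_angle_between <- function(a, b, what = "segment") {
  na <- sqrt(rowSums(a^2))
  nb <- sqrt(rowSums(b^2))
  bad <- which(na <= 1e-6 | nb <= 1e-6)
  if (length(bad)) {
    abort(sprintf("degenerate %s at frame(s) %s", what,
                  paste(utils::head(bad, 10L), collapse = ", ")),
          "ringcast_degenerate_error")
  }
  acos(clamp(rowSums(a * b) / (na * nb), -1, 1)) * 180 / pi
}

#' Differentiate a uniformly sampled series
#'
#' Second-order finite differences: central differences at interior points and
#' one-sided second-order stencils at the two ends. Applying it twice to a
#' theta series yields the angular acceleration. Differentiation is linear:
#' `differentiate(a*f + b*g) = a*differentiate(f) + b*differentiate(g)`
#' exactly.
#'
#' @param series Numeric vector, length >= 3.
#' @param time_s Time stamps with a uniform step (relative tolerance 1e-9).
#' @return Numeric vector of derivatives, same length.
#' @export
differentiate <- function(series, time_s) {
  n <- length(series)
  if (n != length(time_s)) arg_error("series and time_s must have equal length")
  if (n < 3L) arg_error("need at least 3 samples to differentiate")
  dt <- diff(time_s)
  h <- dt[1]
  if (h <= 0 || any(abs(dt - h) > 1e-9 * max(abs(h), 1))) {
    arg_error("time step must be uniform and positive")
  }
  d <- numeric(n)
  d[2:(n - 1L)] <- (series[3:n] - series[1:(n - 2L)]) / (2 * h)
  d[1L] <- (-3 * series[1L] + 4 * series[2L] - series[3L]) / (2 * h)
  d[n] <- (3 * series[n] - 4 * series[n - 1L] + series[n - 2L]) / (2 * h)
  d
}

new_joint_angle_series <- function(time_s, theta1_deg, omega1_deg_s,
                                   alpha1_deg_s2, beta1_deg,
                                   theta2_deg = NULL, theta3_deg = NULL,
                                   cycle_bounds = NULL,
                                   smoothing_window = 1L) {
  n <- length(time_s)
  stopifnot(length(theta1_deg) == n, length(beta1_deg) == n,
            length(omega1_deg_s) == n, length(alpha1_deg_s2) == n)
  structure(
    list(time_s = time_s,
         theta1_deg = theta1_deg,
         omega1_deg_s = omega1_deg_s,
         alpha1_deg_s2 = alpha1_deg_s2,
         beta1_deg = beta1_deg,
         theta2_deg = theta2_deg,
         theta3_deg = theta3_deg,
         cycle_bounds = cycle_bounds,
         smoothing_window = as.integer(smoothing_window)),
    class = "joint_angle_series"
  )
}

#' @export
print.joint_angle_series <- function(x, ...) {
  cat(sprintf("<joint_angle_series> %d frames, theta1 %.1f-%.1f deg, beta1 %.1f-%.1f deg",
              length(x$time_s), min(x$theta1_deg), max(x$theta1_deg),
              min(x$beta1_deg), max(x$beta1_deg)))
  if (!is.null(x$cycle_bounds)) cat(sprintf(", %d cycles", nrow(x$cycle_bounds)))
  cat("\n")
  invisible(x)
}

#' Extract MCP joint angle series from a hand trajectory
#'
#' Computes the middle-finger MCP angle theta1 (from P0->P1 against the Z0
#' axis) and the ring-finger MCP angle beta1 analogously, plus the optional
#' PIP/DIP angles theta2/theta3 (angles between consecutive phalanx vectors of
#' the middle finger). When `smoothing_window > 1`, a centred moving average
#' is applied to all angle series before differentiation; the angular velocity
#' omega1 and acceleration alpha1 are obtained with [differentiate()].
#'
#' @param traj A `hand_trajectory` (see [generate_session()] /
#'   [read_trajectory()]).
#' @param smoothing_window Odd integer >= 1; 1 disables smoothing.
#' @return A `joint_angle_series` (cycle bounds unset; see
#'   [segment_cycles()]).
#' @export
extract_angles <- function(traj, smoothing_window = 1L) {
  stopifnot(inherits(traj, "hand_trajectory"))
  if (smoothing_window < 1 || smoothing_window %% 2 == 0) {
    arg_error("smoothing_window must be a positive odd integer")
  }
  pos <- traj$positions
  seg_m1 <- pos[, 1L, 2L, ] - pos[, 1L, 1L, ]  # middle P0 -> P1
  seg_m2 <- pos[, 1L, 3L, ] - pos[, 1L, 2L, ]
  seg_m3 <- pos[, 1L, 4L, ] - pos[, 1L, 3L, ]
  seg_r1 <- pos[, 2L, 2L, ] - pos[, 2L, 1L, ]  # ring P0 -> P1

  theta1 <- segment_angle_up(seg_m1, what = "middle proximal phalanx")
  beta1 <- segment_angle_up(seg_r1, what = "ring proximal phalanx")
  theta2 <- segment_angle_between(seg_m1, seg_m2, what = "middle PIP segment")
  theta3 <- segment_angle_between(seg_m2, seg_m3, what = "middle DIP segment")

  w <- as.integer(smoothing_window)
  theta1 <- moving_average(theta1, w)
  beta1 <- moving_average(beta1, w)
  theta2 <- moving_average(theta2, w)
  theta3 <- moving_average(theta3, w)

  omega1 <- differentiate(theta1, traj$time_s)
  alpha1 <- differentiate(omega1, traj$time_s)
  new_joint_angle_series(traj$time_s, theta1, omega1, alpha1, beta1,
                         theta2, theta3, smoothing_window = w)
}

#' Segment a joint-angle series into metronome-locked keystroke cycles
#'
#' Fixed-length segmentation aligned to t = 0: the recording is split into
#' `floor(n_frames / frames_per_cycle)` windows of
#' `round(cycle_period_s * sample_rate)` frames; a partial trailing window is
#' discarded. Suitable for metronome-paced recordings where every keystroke
#' occupies exactly one period.
#'
#' @param series A `joint_angle_series` with uniform sampling.
#' @param cycle_period_s Cycle period (s).
#' @return The series with `cycle_bounds` set: an integer matrix with columns
#'   `start` and `end`, 1-based, start inclusive and end exclusive.
#' @export
segment_cycles <- function(series, cycle_period_s = 0.75) {
  stopifnot(inherits(series, "joint_angle_series"))
  if (cycle_period_s <= 0) arg_error("cycle_period_s must be positive")
  n <- length(series$time_s)
  h <- series$time_s[2] - series$time_s[1]
  fpc <- round(cycle_period_s / h)
  if (fpc < 2) arg_error("cycle period must span at least 2 sample intervals")
  n_cycles <- floor(n / fpc)
  if (n_cycles < 1) arg_error("recording shorter than one cycle")
  starts <- (seq_len(n_cycles) - 1L) * fpc + 1L
  series$cycle_bounds <- cbind(start = as.integer(starts),
                               end = as.integer(starts + fpc))
  series
}
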
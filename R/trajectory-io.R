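# Plain-text interchange formats: the trajectory CSV dialect, the angle CSV,
# and the cohort manifest. The dialect is this package's own (the original
# capture logs had no published schema) and is not Leap-Motion-compatible.

TRAJECTORY_COLUMNS <- c("time_s", "subject_id", "set_index", "finger",
                        "joint", "x_mm", "y_mm", "z_mm")

#' @export
as.data.frame.hand_trajectory <- function(x, ...) {
  n <- length(x$time_s)
  fingers <- c("middle", "ring")
  joints <- c("P0", "P1", "P2", "P3")
  # row order: frame-major, then finger, then joint
  grid <- expand.grid(joint = seq_len(4L), finger = seq_len(2L),
                      frame = seq_len(n))
  idx <- cbind(grid$frame, grid$finger, grid$joint)
  data.frame(
    time_s = x$time_s[grid$frame],
    subject_id = x$subject_id,
    set_index = x$set_index,
    finger = fingers[grid$finger],
    joint = joints[grid$joint],
    x_mm = x$positions[cbind(idx, 1L)],
    y_mm = x$positions[cbind(idx, 2L)],
    z_mm = x$positions[cbind(idx, 3L)],
    stringsAsFactors = FALSE
  )
}

#' Write a hand trajectory as CSV
#'
#' One row per (frame, finger, joint) with header
#' `time_s,subject_id,set_index,finger,joint,x_mm,y_mm,z_mm`; coordinates are
#' written with 6 decimal places, which [read_trajectory()] round-trips
#' within 1e-6 mm.
#'
#' @param traj A `hand_trajectory`.
#' @param path Output path.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "hand_trajectory"))
  if (length(traj$time_s) == 0L) arg_error("trajectory has no frames")
  df <- as.data.frame(traj)
  for (col in c("time_s", "x_mm", "y_mm", "z_mm")) {
    df[[col]] <- sprintf("%.6f", df[[col]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a hand trajectory CSV
#'
#' Validates the schema (every required column present), the frame structure
#' (8 rows per frame: 2 fingers x 4 joints), and that the time column is
#' strictly increasing with a uniform step; violations raise classed parse /
#' schema errors naming the offending column or data line.
#'
#' @param path CSV path written by [write_trajectory()].
#' @return A `hand_trajectory`.
#' @export
read_trajectory <- function(path) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) abort(paste0("cannot parse ", path, ": ",
                                     conditionMessage(e)),
                              "ringcast_parse_error")
  )
  missing_cols <- setdiff(TRAJECTORY_COLUMNS, names(df))
  if (length(missing_cols)) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
          "ringcast_schema_error")
  }
  if (nrow(df) == 0L) abort("file contains no frames", "ringcast_parse_error")
  if (nrow(df) %% 8L != 0L) {
    abort("row count is not a multiple of 8 (2 fingers x 4 joints per frame)",
          "ringcast_parse_error")
  }
  n <- nrow(df) %/% 8L
  frame_time <- df$time_s[seq(1L, nrow(df), by = 8L)]
  dt <- diff(frame_time)
  if (any(dt <= 0)) {
    # +1 for the header line when reporting the file line number
    line <- (which(dt <= 0)[1L]) * 8L + 2L
    abort(sprintf("non-monotone time column at line %d", line),
          "ringcast_parse_error")
  }
  if (length(dt) > 1L && any(abs(dt - dt[1L]) > 1e-9 * max(dt[1L], 1))) {
    abort("non-uniform frame time step", "ringcast_parse_error")
  }
  fingers <- c("middle", "ring")
  joints <- c("P0", "P1", "P2", "P3")
  if (!all(df$finger %in% fingers) || !all(df$joint %in% joints)) {
    abort("finger must be middle/ring and joint P0..P3",
          "ringcast_parse_error")
  }
  pos <- array(NA_real_, dim = c(n, 2L, 4L, 3L),
               dimnames = list(NULL, fingers, joints, c("x", "y", "z")))
  fi <- match(df$finger, fingers)
  ji <- match(df$joint, joints)
  fr <- rep(seq_len(n), each = 8L)
  pos[cbind(fr, fi, ji, 1L)] <- df$x_mm
  pos[cbind(fr, fi, ji, 2L)] <- df$y_mm
  pos[cbind(fr, fi, ji, 3L)] <- df$z_mm
  if (anyNA(pos)) {
    abort("incomplete frames: some (finger, joint) cells missing",
          "ringcast_parse_error")
  }
  new_hand_trajectory(df$subject_id[1L], df$set_index[1L], frame_time, pos)
}

#' Write a joint-angle series as CSV
#'
#' Header `time_s,theta1_deg,omega1_deg_s,alpha1_deg_s2,beta1_deg`.
#'
#' @param series A `joint_angle_series`.
#' @param path Output path.
#' @export
write_angles <- function(series, path) {
  stopifnot(inherits(series, "joint_angle_series"))
  utils::write.csv(
    data.frame(time_s = series$time_s,
               theta1_deg = series$theta1_deg,
               omega1_deg_s = series$omega1_deg_s,
               alpha1_deg_s2 = series$alpha1_deg_s2,
               beta1_deg = series$beta1_deg),
    path, row.names = FALSE)
  invisible(path)
}
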
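# Subject covariates and the ground-truth middle->ring coupling law used by
# the synthetic generator.

#' Sample a cohort of synthetic pianist profiles
#'
#' Draws subject covariates matching the study population: middle-finger
#' lengths 84.4 +/- 4.3 mm, ring-finger lengths 79.1 +/- 4.5 mm (truncated to
#' the anatomically plausible 40-130 mm range), and piano training years
#' uniform on a configurable interval.
#'
#' @param n Number of subjects (>= 1).
#' @param middle_mean,middle_sd Mean and SD (mm) of middle-finger length.
#' @param ring_mean,ring_sd Mean and SD (mm) of ring-finger length.
#' @param training_range Length-2 numeric, uniform range of training years.
#' @param length_bounds Truncation bounds (mm) for both finger lengths.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @return A `data.frame` with columns `subject_id` (`"data01"`, ...),
#'   `middle_length_mm`, `ring_length_mm`, `training_years`.
#' @export
#' @examples
#' sample_subjects(3, seed = 1)
sample_subjects <- function(n,
                            middle_mean = 84.4, middle_sd = 4.3,
                            ring_mean = 79.1, ring_sd = 4.5,
                            training_range = c(5, 15),
                            length_bounds = c(40, 130),
                            seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    arg_error("`n` must be a positive integer")
  }
  if (middle_sd < 0 || ring_sd < 0) arg_error("length SDs must be >= 0")
  with_seed(seed, {
    profiles <- data.frame(
      subject_id = sprintf("data%02d", seq_len(n)),
      middle_length_mm = rtruncnorm(n, middle_mean, middle_sd,
                                    length_bounds[1], length_bounds[2]),
      ring_length_mm = rtruncnorm(n, ring_mean, ring_sd,
                                  length_bounds[1], length_bounds[2]),
      training_years = stats::runif(n, training_range[1], training_range[2]),
      stringsAsFactors = FALSE
    )
    validate_profiles(profiles)
    profiles
  })
}

# Truncated normal by rejection; degenerates to the mean when sd == 0.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * (n - length(out)) + 10L, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

validate_profiles <- function(profiles) {
  required <- c("subject_id", "middle_length_mm", "ring_length_mm",
                "training_years")
  missing <- setdiff(required, names(profiles))
  if (length(missing)) {
    arg_error(paste0("profile is missing column(s): ",
                     paste(missing, collapse = ", ")))
  }
  lens <- c(profiles$middle_length_mm, profiles$ring_length_mm)
  if (any(lens <= 40 | lens >= 130)) {
    arg_error("finger lengths must lie in (40, 130) mm")
  }
  if (any(profiles$training_years < 0 | profiles$training_years > 60)) {
    arg_error("training_years must lie in [0, 60]")
  }
  invisible(profiles)
}

#' Define the ground-truth middle-to-ring coupling law
#'
#' The synthetic generator injects a deterministic relationship between the
#' middle-finger MCP angle theta1 and the ring-finger MCP angle beta1 - the
#' "enslaving" coupling that the regression network is later asked to recover:
#'
#'   beta1(t) = offset + gain(profile) * theta1(t - lag)
#'
#' with `gain(profile) = gain_base + gain_length_coeff * (ring - middle length)
#' + gain_training_coeff * training_years`. An optional soft tanh saturation
#' variant bounds the coupled term for robustness experiments.
#'
#' @param gain_base Dimensionless baseline gain.
#' @param gain_length_coeff Gain change per mm of (ring - middle) length
#'   difference.
#' @param gain_training_coeff Gain change per year of piano training.
#' @param lag_s Time lag (s) of the ring response; must lie in
#'   `[0, cycle_period/4]` for the default 0.75 s cycle.
#' @param offset_deg Additive offset (degrees).
#' @param saturation `"none"` (linear, default) or `"tanh"`.
#' @param sat_scale_deg Saturation scale (degrees) for the tanh variant.
#' @return An object of class `coupling_law`.
#' @export
coupling_law <- function(gain_base = 0.8,
                         gain_length_coeff = 0.01,
                         gain_training_coeff = 0.005,
                         lag_s = 0.02,
                         offset_deg = 2,
                         saturation = c("none", "tanh"),
                         sat_scale_deg = 45) {
  saturation <- match.arg(saturation)
  if (lag_s < 0) arg_error("lag_s must be >= 0")
  if (sat_scale_deg <= 0) arg_error("sat_scale_deg must be > 0")
  structure(
    list(gain_base = gain_base,
         gain_length_coeff = gain_length_coeff,
         gain_training_coeff = gain_training_coeff,
         lag_s = lag_s,
         offset_deg = offset_deg,
         saturation = saturation,
         sat_scale_deg = sat_scale_deg),
    class = "coupling_law"
  )
}

#' Evaluate the coupling gain for one or more subject profiles
#'
#' @param law A [coupling_law()].
#' @param profile A profile data.frame (one or more rows) as returned by
#'   [sample_subjects()].
#' @return Numeric vector of gains, one per profile row.
#' @export
coupling_gain <- function(law, profile) {
  stopifnot(inherits(law, "coupling_law"))
  law$gain_base +
    law$gain_length_coeff * (profile$ring_length_mm - profile$middle_length_mm) +
    law$gain_training_coeff * profile$training_years
}
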
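# Feature assembly and min-max normalization for the 3-input (individual) and
# 6-input (multi-individual) network models.

#' Assemble the network's feature table from a joint-angle series
#'
#' The individual model uses the middle-finger MCP motion triplet
#' `(theta1, omega1, alpha1)`; the multi-individual model appends the subject
#' covariates `(ring_length_mm, middle_length_mm, training_years)` as constant
#' columns. The target `beta1_deg` (ring-finger MCP angle) is carried in the
#' last column. Column order is fixed and is the canonical order everywhere in
#' the package.
#'
#' @param series A `joint_angle_series`.
#' @param profile One-row subject profile; required for `mode = "multi"`.
#' @param mode `"individual"` (3 inputs) or `"multi"` (6 inputs).
#' @return A `data.frame` with the input columns followed by `beta1_deg`.
#' @export
build_features <- function(series, profile = NULL,
                           mode = c("individual", "multi")) {
  mode <- match.arg(mode)
  stopifnot(inherits(series, "joint_angle_series"))
  df <- data.frame(theta1_deg = series$theta1_deg,
                   omega1_deg_s = series$omega1_deg_s,
                   alpha1_deg_s2 = series$alpha1_deg_s2)
  if (mode == "multi") {
    if (is.null(profile)) arg_error("multi mode requires a subject profile")
    validate_profiles(profile)
    if (nrow(profile) != 1L) arg_error("profile must be a single row")
    df$ring_length_mm <- rep(profile$ring_length_mm, nrow(df))
    df$middle_length_mm <- rep(profile$middle_length_mm, nrow(df))
    df$training_years <- rep(profile$training_years, nrow(df))
  }
  df$beta1_deg <- series$beta1_deg
  if (anyNA(df)) arg_error("features contain NA")
  df
}

#' Model formula for a feature scope
#'
#' @param mode `"individual"` or `"multi"`.
#' @return A formula with `beta1_deg` as response.
#' @export
feature_formula <- function(mode = c("individual", "multi")) {
  mode <- match.arg(mode)
  if (mode == "individual") {
    beta1_deg ~ theta1_deg + omega1_deg_s + alpha1_deg_s2
  } else {
    beta1_deg ~ theta1_deg + omega1_deg_s + alpha1_deg_s2 +
      ring_length_mm + middle_length_mm + training_years
  }
}

#' Per-column min-max ranges of a feature matrix
#'
#' @param X Numeric matrix (or vector, treated as one column).
#' @return A 2 x k matrix with rows `min` and `max`, one column per feature.
#' @export
feature_ranges <- function(X) {
  X <- as.matrix(X)
  r <- apply(X, 2L, range)
  rownames(r) <- c("min", "max")
  r
}

#' Min-max scale features to `[-1, 1]`
#'
#' Scales each column with ranges captured on the training split:
#' `x' = 2 (x - min) / (max - min) - 1`. Test data scaled with training ranges
#' may legitimately fall outside `[-1, 1]`.
#'
#' @param X Numeric matrix or vector.
#' @param ranges Ranges from [feature_ranges()] computed on training data (a
#'   length-2 vector for a single column).
#' @return Scaled matrix (or vector) of the same shape.
#' @export
normalize_features <- function(X, ranges) {
  vec <- is.null(dim(X))
  X <- as.matrix(X)
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != ncol(X)) arg_error("ranges do not match feature columns")
  span <- ranges[2L, ] - ranges[1L, ]
  degen <- which(span <= 0)
  if (length(degen)) {
    nm <- colnames(X)[degen]
    if (is.null(nm)) nm <- as.character(degen)
    arg_error(paste0("degenerate (constant) feature column(s): ",
                     paste(nm, collapse = ", ")))
  }
  out <- sweep(sweep(X, 2L, ranges[1L, ]), 2L, span / 2, "/") - 1
  if (vec) out[, 1L] else out
}

#' Invert min-max scaling
#'
#' Exact algebraic inverse of [normalize_features()].
#'
#' @inheritParams normalize_features
#' @export
denormalize_features <- function(X, ranges) {
  vec <- is.null(dim(X))
  X <- as.matrix(X)
  ranges <- as.matrix(ranges)
  if (ncol(ranges) != ncol(X)) arg_error("ranges do not match feature columns")
  span <- ranges[2L, ] - ranges[1L, ]
  out <- sweep(sweep(X + 1, 2L, span / 2, "*"), 2L, ranges[1L, ], "+")
  if (vec) out[, 1L] else out
}
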
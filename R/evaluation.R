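# Error metrics, per-cycle worst-case errors, and the two split protocols
# (per-set prefix/suffix and leave-subject-out).

check_pred_actual <- function(pred, actual) {
  if (length(pred) != length(actual)) {
    arg_error("pred and actual must have equal length")
  }
  if (length(pred) == 0L) arg_error("empty error vector")
}

#' Mean absolute error (degrees)
#' @param pred,actual Numeric vectors of equal nonzero length.
#' @export
mae <- function(pred, actual) {
  check_pred_actual(pred, actual)
  mean(abs(pred - actual))
}

#' Root mean square error (degrees)
#' @param pred,actual Numeric vectors of equal nonzero length.
#' @export
rmse <- function(pred, actual) {
  check_pred_actual(pred, actual)
  sqrt(mean((pred - actual)^2))
}

#' Mean absolute percentage error (%)
#'
#' Computed over the frames whose true angle magnitude is at least
#' `floor_deg` (default 1 degree); the near-zero guard prevents the ratio
#' from blowing up when the angle passes near zero. The number of excluded
#' frames is attached as attribute `n_excluded` so the guard is auditable.
#'
#' @param pred,actual Numeric vectors of equal length (degrees).
#' @param floor_deg Exclusion threshold (> 0) on `|actual|`.
#' @return MAPE in percent, with attribute `n_excluded`.
#' @export
mape <- function(pred, actual, floor_deg = 1) {
  check_pred_actual(pred, actual)
  if (floor_deg <= 0) arg_error("floor_deg must be > 0")
  keep <- abs(actual) >= floor_deg
  if (!any(keep)) {
    abort("MAPE undefined: every frame excluded by the magnitude floor",
          "ringcast_metric_error")
  }
  structure(100 * mean(abs(pred[keep] - actual[keep]) / abs(actual[keep])),
            n_excluded = sum(!keep))
}

#' Maximum absolute error per keystroke cycle
#'
#' @param pred,actual Numeric vectors of equal length (degrees).
#' @param cycle_bounds Integer matrix with columns `start`, `end` (1-based,
#'   end exclusive), as set by [segment_cycles()].
#' @return Numeric vector, one maximum per cycle.
#' @export
per_cycle_max_abs_error <- function(pred, actual, cycle_bounds) {
  check_pred_actual(pred, actual)
  cb <- as.matrix(cycle_bounds)
  if (any(cb[, 2L] <= cb[, 1L])) arg_error("empty cycle window")
  if (any(cb[, 1L] < 1L) || any(cb[, 2L] > length(pred) + 1L)) {
    arg_error("cycle bounds outside series range")
  }
  err <- abs(pred - actual)
  vapply(seq_len(nrow(cb)),
         function(i) max(err[cb[i, 1L]:(cb[i, 2L] - 1L)]),
         numeric(1))
}

#' Prefix/suffix split of recording sets
#'
#' Order-preserving split with no shuffling: the first `n_train` sets train
#' the model and the remaining sets are held out (the study protocol's
#' "first 80 / last 20" design).
#'
#' @param sets A list of sets (any element type).
#' @param n_train Number of leading sets for training; must be in
#'   `[1, length(sets) - 1]`.
#' @return A list with elements `train` and `test`.
#' @export
split_per_set <- function(sets, n_train) {
  n <- length(sets)
  if (n_train < 1 || n_train >= n) {
    arg_error("n_train must be in [1, number of sets - 1]")
  }
  list(train = sets[seq_len(n_train)], test = sets[seq.int(n_train + 1L, n)])
}

#' Leave-subject-out split of a cohort
#'
#' All sets of the held-out subject form the test partition; every other
#' subject's sets train the model.
#'
#' @param cohort Named list (names = subject ids) or list of elements carrying
#'   a `subject_id` field.
#' @param test_subject_id Subject id to hold out.
#' @return A list with elements `train` and `test` (sub-lists of `cohort`).
#' @export
split_leave_subject_out <- function(cohort, test_subject_id) {
  ids <- names(cohort)
  if (is.null(ids)) {
    ids <- vapply(cohort, function(x) x$subject_id, character(1))
  }
  hit <- ids == test_subject_id
  if (!any(hit)) arg_error(paste0("unknown subject id: ", test_subject_id))
  list(train = cohort[!hit], test = cohort[hit])
}

#' Build an evaluation report for one model on one split
#'
#' Computes MAE, RMSE and MAPE over all test frames (frame-wise, not
#' cycle-averaged) plus the per-cycle maximum absolute errors.
#'
#' @param pred,actual Predicted and measured ring-finger MCP angles
#'   (degrees).
#' @param cycle_bounds Cycle windows of the test series (may be `NULL` to
#'   skip the per-cycle summary).
#' @param model_variant `"bp"`, `"ga-bp"` or `"ssa-bp"`.
#' @param scope `"individual"` or `"multi"`.
#' @param split_descriptor Free-form list describing the split.
#' @param seed Seed used for the run (recorded for provenance).
#' @param mape_floor_deg Magnitude floor passed to [mape()].
#' @return An object of class `eval_report`.
#' @export
eval_report <- function(pred, actual, cycle_bounds = NULL,
                        model_variant = "bp",
                        scope = c("individual", "multi"),
                        split_descriptor = list(), seed = NA_integer_,
                        mape_floor_deg = 1) {
  scope <- match.arg(scope)
  mp <- mape(pred, actual, mape_floor_deg)
  per_cycle <- if (is.null(cycle_bounds)) numeric(0) else {
    per_cycle_max_abs_error(pred, actual, cycle_bounds)
  }
  structure(
    list(model_variant = model_variant,
         scope = scope,
         mae_deg = mae(pred, actual),
         rmse_deg = rmse(pred, actual),
         mape_pct = as.numeric(mp),
         mape_excluded_frames = attr(mp, "n_excluded"),
         mape_floor_deg = mape_floor_deg,
         per_cycle_max_abs_err_deg = per_cycle,
         n_frames = length(pred),
         split_descriptor = split_descriptor,
         seed = seed),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s (%s scope), %d test frames\n",
              x$model_variant, x$scope, x$n_frames))
  cat(sprintf("  MAE %.4f deg | RMSE %.4f deg | MAPE %.4f%% (%d frames below %.3g deg excluded)\n",
              x$mae_deg, x$rmse_deg, x$mape_pct, x$mape_excluded_frames,
              x$mape_floor_deg))
  if (length(x$per_cycle_max_abs_err_deg)) {
    cat(sprintf("  per-cycle max |err|: median %.3f deg, worst %.3f deg over %d cycles\n",
                stats::median(x$per_cycle_max_abs_err_deg),
                max(x$per_cycle_max_abs_err_deg),
                length(x$per_cycle_max_abs_err_deg)))
  }
  invisible(x)
}

#' Serialize / read an evaluation report (JSON)
#'
#' Round-trips every numeric field losslessly (full double precision).
#'
#' @param report An `eval_report`.
#' @param path File path.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$per_cycle_max_abs_err_deg <- as.numeric(x$per_cycle_max_abs_err_deg)
  if (is.null(x$split_descriptor)) x$split_descriptor <- list()
  structure(x, class = "eval_report")
}

#' Aggregate reports into a study-style metrics table
#'
#' @param reports A list of `eval_report`s.
#' @return A `data.frame` with columns `model`, `mae_deg`, `rmse_deg`,
#'   `mape_pct`, one row per report.
#' @export
aggregate_reports <- function(reports) {
  data.frame(
    model = vapply(reports, function(r) r$model_variant, character(1)),
    mae_deg = vapply(reports, function(r) r$mae_deg, numeric(1)),
    rmse_deg = vapply(reports, function(r) r$rmse_deg, numeric(1)),
    mape_pct = vapply(reports, function(r) r$mape_pct, numeric(1)),
    stringsAsFactors = FALSE
  )
}
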